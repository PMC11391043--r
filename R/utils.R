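## Physical constants shared across the energetics code.

#' Physical constants used by the energetics routines
#'
#' @description
#' * `kB`: Boltzmann constant, 0.0019872041 kcal/(mol K).
#' * `coulomb`: electrostatic conversion factor, 332.0636 kcal A/(mol e^2),
#'   so that `coulomb * q1 * q2 / r` is in kcal/mol for charges in e and
#'   distances in Angstrom.
#' * `eps_solvent`: solvent dielectric (80) used by the Generalized-Born
#'   polar solvation surrogate.
#' * `gamma_np`: surface-tension coefficient for the nonpolar solvation
#'   term, 0.0072 kcal/(mol A^2).
#' @format A named list.
#' @export
phbind_constants <- list(
  kB          = 0.0019872041,
  coulomb     = 332.0636,
  eps_solvent = 80,
  gamma_np    = 0.0072
)

## Element defaults used when a PDB lacks topology annotations.
.element_radius <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
.element_mass   <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)

.default_radius <- function(element) {
  r <- .element_radius[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

.default_mass <- function(element) {
  m <- .element_mass[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

## round-half-up at `digits`, matching how the source tables were printed
## (base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

## numerically stable log(mean(exp(x)))
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
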