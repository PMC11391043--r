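#' Receptor-ligand interaction energy of one frame
#'
#' For pairwise-additive potentials, the complex-minus-parts interaction
#' energy `E_complex - (E_receptor + E_ligand)` reduces exactly to the
#' receptor-ligand cross terms, which is what is computed:
#' electrostatics `sum 332.0636 q_i q_j / r_ij` (kcal/mol, charges in e,
#' distances in Angstrom) and Lennard-Jones
#' `sum eps_ij [ (rmin_ij/r)^12 - 2 (rmin_ij/r)^6 ]` with
#' `eps_ij = sqrt(eps_i eps_j)` and `rmin_ij = rmin_half_i + rmin_half_j`.
#' No cutoff and no periodicity: toy systems are small and exactness
#' beats speed.
#'
#' @param frame n x 3 coordinate matrix (Angstrom); defaults to the
#'   system's own coordinates.
#' @param system a `molecular_system` with charges, LJ parameters and a
#'   receptor/ligand partition.
#' @return named numeric vector `c(ele =, vdw =, total =)` in kcal/mol.
#' @export
interaction_energy <- function(frame = NULL, system) {
  if (!inherits(system, "molecular_system"))
    .stopf("system must be a molecular_system")
  if (!length(system$receptor) || !length(system$ligand))
    .stopf("system needs non-empty receptor and ligand groups")
  xyz <- frame %||% coords(system)
  a <- system$atoms
  ri <- system$receptor; li <- system$ligand
  P <- xyz[ri, , drop = FALSE]
  Q <- xyz[li, , drop = FALSE]
  ## pairwise distances receptor x ligand
  d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q)
  d <- sqrt(pmax(d2, 0))

  qq <- outer(a$charge[ri], a$charge[li])
  close <- d < 1e-6 & abs(qq) > 0
  if (any(close)) {
    w <- which(close, arr.ind = TRUE)[1L, ]
    .stopf("singular charged pair: receptor atom %d and ligand atom %d coincide",
           ri[w[1L]], li[w[2L]])
  }
  ele <- phbind_constants$coulomb * sum(qq / d)

  eij <- sqrt(outer(a$epsilon[ri], a$epsilon[li]))
  rmin <- outer(a$rmin_half[ri], a$rmin_half[li], `+`)
  sr6 <- (rmin / d)^6
  vdw_terms <- eij * (sr6^2 - 2 * sr6)
  vdw_terms[eij == 0] <- 0
  vdw <- sum(vdw_terms)
  c(ele = ele, vdw = vdw, total = ele + vdw)
}

## internal constructor shared by simulate_energy_series() and
## energy_series()
new_energy_series <- function(ele, vdw, times, temperature) {
  if (temperature <= 0) .stopf("temperature must be > 0")
  structure(list(ele = ele, vdw = vdw, total = ele + vdw, times = times,
                 temperature = temperature,
                 beta = 1 / (phbind_constants$kB * temperature)),
            class = "energy_series")
}

#' Per-frame interaction-energy series of a trajectory
#'
#' Applies [interaction_energy()] to every frame and records the inverse
#' temperature `beta = 1/(kB T)` needed by the interaction-entropy
#' estimator.
#'
#' @param traj a [trajectory()].
#' @param system the parameterised `molecular_system` (default: the
#'   trajectory's own system).
#' @param temperature temperature in K (default 300).
#' @return An `energy_series`: list with per-frame `ele`, `vdw`, `total`
#'   (kcal/mol), `times`, `temperature`, `beta`.
#' @export
energy_series <- function(traj, system = traj$system, temperature = 300) {
  e <- vapply(traj$frames, interaction_energy, numeric(3), system = system)
  new_energy_series(ele = e["ele", ], vdw = e["vdw", ], times = traj$times,
                    temperature = temperature)
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf(
    "energy_series: %d frames at %g K; <dE_int> = %.3f kcal/mol (ele %.3f, vdw %.3f), sd %.3f\n",
    length(x$total), x$temperature, mean(x$total), mean(x$ele), mean(x$vdw),
    stats::sd(x$total)))
  invisible(x)
}

#' Interaction-entropy estimate of -T dS
#'
#' Computes the interaction-entropy estimator
#' `-T dS = kB T log( (1/N) sum_i exp(beta dE_fluct(t_i)) )` from the
#' fluctuation `dE_fluct = dE_int - <dE_int>` of the per-frame
#' receptor-ligand interaction energy, via a log-sum-exp stable form.
#' The result is >= 0 by Jensen's inequality, equals 0 only for a
#' constant series, and for Gaussian fluctuations of standard deviation
#' sigma converges to `beta sigma^2 / 2`.
#'
#' Mean-centering is the default: exponentiating the raw energy instead
#' of its fluctuation makes the average diverge whenever `|<dE>| >> kB T`
#' and merely adds `beta <dE>` inside the log otherwise.  `center =
#' FALSE` evaluates that literal form (stable via log-sum-exp) for
#' auditability.
#'
#' @param series an `energy_series`.
#' @param center subtract the mean energy before exponentiating
#'   (default TRUE).
#' @return `-T dS` in kcal/mol.
#' @export
interaction_entropy <- function(series, center = TRUE) {
  if (!inherits(series, "energy_series"))
    .stopf("series must be an energy_series")
  e <- series$total
  if (length(e) < 2) .stopf("interaction entropy needs >= 2 frames")
  if (anyNA(e)) .stopf("NaN/NA in energy series")
  if (center) e <- e - mean(e)
  kBT <- 1 / series$beta
  kBT * log_mean_exp(series$beta * e)
}

#' Generalized-Born surrogate for the polar + nonpolar solvation energy
#'
#' The polar term uses the Still pairwise Generalized-Born functional
#' with effective Born radii from the Coulomb-field pairwise-descreening
#' (HCT) approximation, interior dielectric 1 and solvent dielectric 80;
#' for an isolated charge it reduces exactly to the Born ion formula
#' `-166.0318 (1 - 1/80) q^2 / R`.  The nonpolar term is
#' `gamma * SASA` with gamma = 0.0072 kcal/(mol A^2) and a 1.4 A probe.
#' This surrogate stands in for a finite-difference Poisson-Boltzmann
#' solver; outputs label the polar column `pb_surrogate(GB)`.
#'
#' @param frame n x 3 coordinates (Angstrom); default: system coordinates.
#' @param system a `molecular_system` with charges and Born radius seeds.
#' @param subset `"complex"`, `"receptor"` or `"ligand"`: which atom group
#'   to evaluate.
#' @param probe_radius,n_sphere_points SASA settings for the nonpolar term.
#' @return named vector `c(dG_pb = , dG_np = )` in kcal/mol (`dG_pb` is
#'   the GB surrogate).
#' @export
solvation_energy <- function(frame = NULL, system,
                             subset = c("complex", "receptor", "ligand"),
                             probe_radius = 1.4, n_sphere_points = 960L) {
  subset <- match.arg(subset)
  xyz <- frame %||% coords(system)
  idx <- switch(subset,
                complex = seq_len(nrow(system$atoms)),
                receptor = system$receptor,
                ligand = system$ligand)
  if (!length(idx)) .stopf("empty atom subset '%s'", subset)
  q <- system$atoms$charge[idx]
  rho <- system$atoms$radius[idx]
  if (any(!is.finite(rho)) || any(rho <= 0)) .stopf("missing Born radii")
  x <- xyz[idx, , drop = FALSE]

  Rb <- .born_radii(x, rho)
  dG_pb <- .gb_still(x, q, Rb, phbind_constants$eps_solvent)
  dG_np <- phbind_constants$gamma_np *
    sasa(x, radii = rho, probe_radius = probe_radius,
         n_sphere_points = n_sphere_points)$total * 100  # nm^2 -> A^2
  c(dG_pb = dG_pb, dG_np = dG_np)
}

## HCT pairwise-descreening effective Born radii (Coulomb-field
## approximation): 1/R_i = 1/rho_i - sum_j H(r_ij, rho_i, rho_j)
.born_radii <- function(x, rho) {
  n <- nrow(x)
  inv <- 1 / rho
  if (n > 1) {
    d <- as.matrix(stats::dist(x))
    for (i in seq_len(n)) {
      for (j in seq_len(n)[-i]) {
        r <- d[i, j]
        U <- r + rho[j]
        if (U <= rho[i]) next  # i engulfs j: no descreening in this approx.
        L <- max(rho[i], r - rho[j])
        H <- 0.5 * (1 / L - 1 / U +
                      (r / 4) * (1 / U^2 - 1 / L^2) +
                      (1 / (2 * r)) * log(L / U) +
                      (rho[j]^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
        inv[i] <- inv[i] - H
      }
    }
  }
  ## clamp: heavy descreening can push 1/R negative in pathological overlaps
  pmax(1 / inv, rho)
}

## Still GB polar solvation energy (self terms included)
.gb_still <- function(x, q, Rb, eps_w) {
  n <- nrow(x)
  pref <- -0.5 * phbind_constants$coulomb * (1 - 1 / eps_w)
  total <- sum(pref * q^2 / Rb)  # self (Born) terms
  if (n > 1) {
    d2 <- as.matrix(stats::dist(x))^2
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        RiRj <- Rb[i] * Rb[j]
        fgb <- sqrt(d2[i, j] + RiRj * exp(-d2[i, j] / (4 * RiRj)))
        total <- total + 2 * pref * q[i] * q[j] / fgb
      }
    }
  }
  total
}

#' Binding free-energy summary from aggregated terms
#'
#' Assembles the MM-PBSA-style term table with its composition identities
#' enforced exactly: `dG_gas = dG_ele + dG_vdw`, `dG_sol = dG_np + dG_pb`,
#' `dG_mmpbsa = dG_gas + dG_sol`, and `dG_bind = dG_mmpbsa + minus_TdS`
#' under the default literal-sum convention.  `convention = "paper-sign"`
#' instead reports `-|dG_mmpbsa + minus_TdS| * sign(dG_mmpbsa)`, mirroring
#' published tables in which the bind column carries the sign of the
#' enthalpic part.
#'
#' Published tables often print only the aggregated `dG_gas` and `dG_sol`
#' columns; these may be supplied directly instead of the four components,
#' in which case the component fields are `NA`.
#'
#' @param dG_ele,dG_vdw,dG_np,dG_pb component terms (kcal/mol).
#' @param minus_TdS interaction-entropy term (kcal/mol).
#' @param dG_gas,dG_sol aggregated terms; computed from the components
#'   when omitted.
#' @param n_frames number of frames behind the averages (metadata).
#' @param convention `"sum"` (default) or `"paper-sign"`.
#' @return An object of class `free_energy_summary`.
#' @export
free_energy_summary <- function(dG_ele = NA_real_, dG_vdw = NA_real_,
                                dG_np = NA_real_, dG_pb = NA_real_,
                                minus_TdS = 0,
                                dG_gas = NULL, dG_sol = NULL,
                                n_frames = NA_integer_,
                                convention = c("sum", "paper-sign")) {
  convention <- match.arg(convention)
  dG_gas <- dG_gas %||% (dG_ele + dG_vdw)
  dG_sol <- dG_sol %||% (dG_np + dG_pb)
  if (is.na(dG_gas) || is.na(dG_sol))
    .stopf("either the components or dG_gas/dG_sol must be given")
  dG_mmpbsa <- dG_gas + dG_sol
  raw <- dG_mmpbsa + minus_TdS
  dG_bind <- if (convention == "sum") raw else sign(dG_mmpbsa) * abs(raw)
  structure(
    list(dG_ele = dG_ele, dG_vdw = dG_vdw, dG_gas = dG_gas,
         dG_np = dG_np, dG_pb = dG_pb, dG_sol = dG_sol,
         dG_mmpbsa = dG_mmpbsa, minus_TdS = minus_TdS, dG_bind = dG_bind,
         n_frames = n_frames, convention = convention,
         polar_model = "pb_surrogate(GB)"),
    class = "free_energy_summary")
}

#' @export
print.free_energy_summary <- function(x, ...) {
  cat("Binding free-energy summary (kcal/mol)\n")
  cat(sprintf("  dG_ele    %8.2f\n  dG_vdw    %8.2f\n  dG_gas    %8.2f\n",
              x$dG_ele, x$dG_vdw, x$dG_gas))
  cat(sprintf("  dG_np     %8.2f\n  %-9s %8.2f\n  dG_sol    %8.2f\n",
              x$dG_np, x$polar_model, x$dG_pb, x$dG_sol))
  cat(sprintf("  dG_mmpbsa %8.2f\n  -TdS      %8.2f\n  dG_bind   %8.2f  [%s]\n",
              x$dG_mmpbsa, x$minus_TdS, x$dG_bind, x$convention))
  if (!is.na(x$n_frames)) cat(sprintf("  frames: %d\n", x$n_frames))
  invisible(x)
}

#' @export
as.data.frame.free_energy_summary <- function(x, ...) {
  data.frame(dG_ele = x$dG_ele, dG_vdw = x$dG_vdw, dG_gas = x$dG_gas,
             dG_np = x$dG_np, dG_pb = x$dG_pb, dG_sol = x$dG_sol,
             dG_mmpbsa = x$dG_mmpbsa, minus_TdS = x$minus_TdS,
             dG_bind = x$dG_bind)
}

#' End-to-end MM-PBSA-style summary of a trajectory
#'
#' Single-trajectory approximation: receptor and ligand conformations are
#' taken from the complex trajectory.  `dG_ele`/`dG_vdw` are frame means
#' of the gas-phase interaction components; `dG_pb`/`dG_np` are frame
#' means of the `complex - receptor - ligand` solvation difference
#' (polar term: GB surrogate); `minus_TdS` comes from
#' [interaction_entropy()] on the per-frame interaction energy.
#'
#' @param traj a [trajectory()].
#' @param system parameterised system (default: the trajectory's).
#' @param temperature K (default 300).
#' @param solvation_stride evaluate the (costly) solvation difference on
#'   every `solvation_stride`-th frame (default 1 = all frames).
#' @param n_sphere_points SASA lattice size for the nonpolar term.
#' @param convention `dG_bind` sign convention, see
#'   [free_energy_summary()].
#' @return A `free_energy_summary`.
#' @export
mmpbsa_summary <- function(traj, system = traj$system, temperature = 300,
                           solvation_stride = 1L, n_sphere_points = 960L,
                           convention = c("sum", "paper-sign")) {
  es <- energy_series(traj, system, temperature)
  sol_frames <- seq(1L, n_frames(traj), by = solvation_stride)
  sol <- vapply(traj$frames[sol_frames], function(f) {
    cx <- solvation_energy(f, system, "complex", n_sphere_points = n_sphere_points)
    rc <- solvation_energy(f, system, "receptor", n_sphere_points = n_sphere_points)
    lg <- solvation_energy(f, system, "ligand", n_sphere_points = n_sphere_points)
    cx - rc - lg
  }, numeric(2))
  free_energy_summary(
    dG_ele = mean(es$ele), dG_vdw = mean(es$vdw),
    dG_np = mean(sol["dG_np", ]), dG_pb = mean(sol["dG_pb", ]),
    minus_TdS = interaction_entropy(es),
    n_frames = n_frames(traj), convention = match.arg(convention))
}

#' Per-residue decomposition of the interaction energy
#'
#' Splits the frame-averaged gas-phase receptor-ligand interaction energy
#' into per-receptor-residue contributions
#' `sum_{i in residue, j in ligand} (ele_ij + vdw_ij)`.  Because the
#' pairwise sum is exactly additive, the contributions sum to the total
#' mean interaction energy to machine precision.
#'
#' @param traj a [trajectory()].
#' @param system parameterised system (default: the trajectory's).
#' @return A `residue_contribution`: data.frame with columns `resnum`,
#'   `resname`, `energy` (kcal/mol, frame mean).
#' @export
residue_decomposition <- function(traj, system = traj$system) {
  if (!length(system$receptor) || !length(system$ligand))
    .stopf("system needs non-empty receptor and ligand groups")
  a <- system$atoms
  ri <- system$receptor; li <- system$ligand
  res_of <- a$resnum[ri]
  acc <- NULL
  for (f in traj$frames) {
    P <- f[ri, , drop = FALSE]
    Q <- f[li, , drop = FALSE]
    d <- sqrt(pmax(outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q), 0))
    ele <- phbind_constants$coulomb * outer(a$charge[ri], a$charge[li]) / d
    eij <- sqrt(outer(a$epsilon[ri], a$epsilon[li]))
    sr6 <- (outer(a$rmin_half[ri], a$rmin_half[li], `+`) / d)^6
    vdw <- eij * (sr6^2 - 2 * sr6)
    vdw[eij == 0] <- 0
    per_atom <- rowSums(ele + vdw)
    per_res <- tapply(per_atom, res_of, sum)
    acc <- if (is.null(acc)) per_res else acc + per_res
  }
  per_res <- acc / length(traj$frames)
  resnum <- as.integer(names(per_res))
  resname <- a$resname[ri][match(resnum, res_of)]
  out <- data.frame(resnum = resnum, resname = resname,
                    energy = as.numeric(per_res))
  out <- out[order(out$resnum), ]
  rownames(out) <- NULL
  class(out) <- c("residue_contribution", "data.frame")
  out
}

#' Top binding-energy contributors
#'
#' Ranks residues by most-negative (most favourable) interaction energy;
#' ties broken by residue number.
#'
#' @param contrib a `residue_contribution` from [residue_decomposition()].
#' @param k number of residues to return (capped at the residue count).
#' @return data.frame of the top-k rows, ranked.
#' @export
rank_contributors <- function(contrib, k = 5L) {
  if (k < 1) .stopf("k must be >= 1")
  o <- order(contrib$energy, contrib$resnum)
  out <- contrib[o, , drop = FALSE][seq_len(min(k, nrow(contrib))), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
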