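#' Specification of a toy receptor-ligand complex
#'
#' Parameters for [make_toy_complex()].  The defaults give a compact
#' helix-like receptor of 12 five-atom residues with an 8-atom ligand
#' docked into a shallow pocket -- large enough to exercise every analysis
#' stage, small enough that exact O(N^2) energetics stay instantaneous.
#'
#' @param n_receptor_residues number of receptor residues (>= 1).
#' @param atoms_per_residue atoms per receptor residue (>= 1; the first
#'   three are named N, CA, C so backbone/C-alpha selections work).
#' @param ligand_atoms number of ligand atoms (>= 1).
#' @param charge_scale scale (e) of the uniform partial-charge draw before
#'   the shift that makes each group's net charge exactly integer (zero).
#' @param seed RNG seed; every generator here is a pure function of its
#'   arguments including the seed.
#' @return A list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_receptor_residues = 12L, atoms_per_residue = 5L,
                             ligand_atoms = 8L, charge_scale = 0.2,
                             seed = 1L) {
  if (n_receptor_residues < 1 || atoms_per_residue < 1 || ligand_atoms < 1)
    .stopf("all toy-complex counts must be >= 1")
  structure(list(n_receptor_residues = as.integer(n_receptor_residues),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 ligand_atoms = as.integer(ligand_atoms),
                 charge_scale = charge_scale, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

#' Generate a toy receptor-ligand complex
#'
#' The receptor is laid out as a helix-like curve (radius 2.3 A, rise
#' 1.5 A, 100 degrees per residue), each residue carrying
#' `atoms_per_residue` atoms jittered around its backbone position.  The
#' ligand is placed at the centroid of the central receptor residues so it
#' sits in a pocket within 6 A of several residues.  Partial charges are
#' drawn uniformly then shifted so receptor and ligand net charges are
#' each exactly 0; Lennard-Jones parameters and Born radii are positive.
#'
#' @param spec a [toy_complex_spec()].
#' @return A [molecular_system()] with receptor/ligand partition set.
#' @examples
#' sys <- make_toy_complex(toy_complex_spec(seed = 42))
#' length(sys$ligand)
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  if (!inherits(spec, "toy_complex_spec")) .stopf("spec must be a toy_complex_spec")
  rng <- .seeded_rng(spec$seed)
  nres <- spec$n_receptor_residues
  apr <- spec$atoms_per_residue

  ## helix-like backbone curve; the 5 A radius leaves a hollow axial
  ## channel that serves as the ligand pocket
  ang <- (seq_len(nres) - 1) * 100 * pi / 180
  centers <- cbind(5.0 * cos(ang), 5.0 * sin(ang), 1.5 * (seq_len(nres) - 1))

  ## anchor atom (on the curve) is the C-alpha
  names_pool <- c("CA", "N", "C", "O", "CB", paste0("C", 1:50))
  elem_pool <- c("C", "N", "C", "O", "C", rep("C", 50))
  rec <- do.call(rbind, lapply(seq_len(nres), function(i) {
    offs <- matrix(rng$runif(apr * 3, -0.6, 0.6), ncol = 3)
    offs[1, ] <- 0  # keep the backbone anchor on the curve
    data.frame(
      name = names_pool[seq_len(apr)],
      element = elem_pool[seq_len(apr)],
      resname = "GLY",
      resnum = i,
      chain = "A",
      x = centers[i, 1] + offs[, 1],
      y = centers[i, 2] + offs[, 2],
      z = centers[i, 3] + offs[, 3],
      stringsAsFactors = FALSE)
  }))
  ## ligand pocket: on the helix axis at the height of the central
  ## residues, inside the channel and < 6 A from several residue anchors
  mid <- seq(max(1L, floor(nres / 3)), min(nres, ceiling(2 * nres / 3)))
  pocket <- c(0, 0, mean(centers[mid, 3]))
  lig_off <- matrix(rng$runif(spec$ligand_atoms * 3, -1.0, 1.0), ncol = 3)
  lig <- data.frame(
    name = paste0("L", seq_len(spec$ligand_atoms)),
    element = "C",
    resname = "LIG",
    resnum = 1L,
    chain = "L",
    x = pocket[1] + lig_off[, 1],
    y = pocket[2] + lig_off[, 2],
    z = pocket[3] + lig_off[, 3],
    stringsAsFactors = FALSE)

  atoms <- rbind(rec, lig)
  n_rec <- nrow(rec)
  n_lig <- nrow(lig)
  q <- rng$runif(n_rec + n_lig, -spec$charge_scale, spec$charge_scale)
  q[seq_len(n_rec)] <- q[seq_len(n_rec)] - mean(q[seq_len(n_rec)])
  q[n_rec + seq_len(n_lig)] <- q[n_rec + seq_len(n_lig)] -
    mean(q[n_rec + seq_len(n_lig)])
  atoms$charge <- q
  atoms$epsilon <- rng$runif(n_rec + n_lig, 0.05, 0.20)
  atoms$rmin_half <- rng$runif(n_rec + n_lig, 1.2, 1.6)
  atoms$radius <- .default_radius(atoms$element)
  atoms$mass <- .default_mass(atoms$element)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$group <- c(rep("R", n_rec), rep("L", n_lig))
  molecular_system(atoms)
}

#' Specification of per-frame coordinate fluctuations
#'
#' Parameters for [simulate_trajectory()].  Frames are the reference
#' structure plus independent isotropic Gaussian displacements: scale
#' `sigma_core` for ordinary atoms and `sigma_loose` for atoms in
#' `loose_selection` residues.  The loose set is the pH-like control: a
#' destabilised (low-pH-like) condition is emulated by inflating
#' `sigma_loose` over part of the chain.
#'
#' @param n_frames number of frames (>= 2).
#' @param sigma_core per-coordinate displacement scale (A) for stable atoms.
#' @param sigma_loose displacement scale (A) for loose residues.
#' @param loose_selection receptor residue numbers that fluctuate with
#'   `sigma_loose`.
#' @param dt time step between frames (ns).
#' @param rho optional AR(1) autocorrelation of successive displacements
#'   (0 = independent frames, the default, under which the RMSF and
#'   interaction-entropy closed forms hold exactly in expectation).
#' @param seed RNG seed.
#' @return A list of class `fluctuation_spec`.
#' @export
fluctuation_spec <- function(n_frames = 200L, sigma_core = 0.3,
                             sigma_loose = 0.9, loose_selection = integer(0),
                             dt = 0.02, rho = 0, seed = 1L) {
  if (n_frames < 2) .stopf("n_frames must be >= 2")
  if (sigma_core < 0 || sigma_loose < 0) .stopf("sigmas must be >= 0")
  if (rho < 0 || rho >= 1) .stopf("rho must be in [0, 1)")
  structure(list(n_frames = as.integer(n_frames), sigma_core = sigma_core,
                 sigma_loose = sigma_loose,
                 loose_selection = as.integer(loose_selection),
                 dt = dt, rho = rho, seed = as.integer(seed)),
            class = "fluctuation_spec")
}

#' Simulate a fluctuating trajectory around a reference structure
#'
#' @param system a `molecular_system` providing the reference coordinates.
#' @param fluct a [fluctuation_spec()].
#' @return A [trajectory()] with `fluct$n_frames` frames at times
#'   `0, dt, 2 dt, ...` ns.
#' @export
simulate_trajectory <- function(system, fluct = fluctuation_spec()) {
  if (!inherits(system, "molecular_system"))
    .stopf("system must be a molecular_system")
  if (!inherits(fluct, "fluctuation_spec"))
    .stopf("fluct must be a fluctuation_spec")
  extra <- setdiff(fluct$loose_selection, system$atoms$resnum[system$receptor])
  if (length(extra))
    .stopf("loose_selection contains residue number(s) not in the receptor: %s",
           paste(extra, collapse = ", "))
  rng <- .seeded_rng(fluct$seed)
  ref <- coords(system)
  n <- nrow(ref)
  sig <- rep(fluct$sigma_core, n)
  loose <- system$atoms$resnum %in% fluct$loose_selection &
    seq_len(n) %in% system$receptor
  sig[loose] <- fluct$sigma_loose
  frames <- vector("list", fluct$n_frames)
  disp <- matrix(0, n, 3)
  scale_innov <- if (fluct$rho > 0) sqrt(1 - fluct$rho^2) else 1
  for (f in seq_len(fluct$n_frames)) {
    innov <- matrix(rng$rnorm(n * 3), n, 3) * sig
    disp <- if (fluct$rho > 0) fluct$rho * disp + scale_innov * innov else innov
    frames[[f]] <- ref + disp
  }
  trajectory(system, frames, times = (seq_len(fluct$n_frames) - 1) * fluct$dt)
}

#' Simulate a Gaussian per-frame interaction-energy series
#'
#' Draws i.i.d. Gaussian per-frame receptor-ligand interaction energies --
#' the setting in which the interaction-entropy estimator has the closed
#' form -T dS -> beta sigma^2 / 2.  The total is split into electrostatic
#' and van der Waals halves (each Gaussian) so the component-sum invariant
#' of [energy_series()] objects holds.
#'
#' @param mean mean interaction energy (kcal/mol).
#' @param sigma standard deviation (kcal/mol, >= 0).
#' @param n number of frames (>= 2).
#' @param temperature temperature (K) recorded on the series.
#' @param seed RNG seed.
#' @return An `energy_series` object (see [energy_series()]).
#' @export
simulate_energy_series <- function(mean, sigma, n, temperature = 300,
                                   seed = 1L) {
  if (n < 2) .stopf("n must be >= 2")
  if (sigma < 0) .stopf("sigma must be >= 0")
  rng <- .seeded_rng(seed)
  ele <- rng$rnorm(n, mean / 2, sigma / sqrt(2))
  vdw <- rng$rnorm(n, mean / 2, sigma / sqrt(2))
  new_energy_series(ele = ele, vdw = vdw, times = seq_len(n) - 1,
                    temperature = temperature)
}

#' Simulate a noisy one-site saturation titration
#'
#' Inverts the one-site binding model Y = Bmax X / (Kd + X) and applies
#' multiplicative Gaussian noise `Y * (1 + N(0, noise_cv))` per replicate
#' observation (fluorescence error scales with intensity), clipped at 0.
#'
#' @param kd ground-truth dissociation constant (uM, > 0).
#' @param bmax maximal specific fluorescence (counts/s, > 0).
#' @param concentrations probe concentrations (uM); default is the
#'   nine-point 0-12 uM design used in the motivating assay.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates replicates per concentration (default 3).
#' @param ph_label condition label attached to the series.
#' @param seed RNG seed.
#' @return A [titration_series()].
#' @export
simulate_titration <- function(kd, bmax,
                               concentrations = c(0, 0.5, 1, 2, 4, 6, 8, 10, 12),
                               noise_cv = 0.02, n_replicates = 3L,
                               ph_label = "", seed = 1L) {
  if (kd <= 0 || bmax <= 0) .stopf("kd and bmax must be > 0")
  if (noise_cv < 0) .stopf("noise_cv must be >= 0")
  rng <- .seeded_rng(seed)
  conc <- rep(concentrations, each = n_replicates)
  y <- bmax * conc / (kd + conc)
  y <- pmax(0, y * (1 + rng$rnorm(length(y), 0, noise_cv)))
  titration_series(conc, y, replicate = rep(seq_len(n_replicates),
                                            times = length(concentrations)),
                   ph_label = ph_label)
}

#' Simulate a noisy one-site competitive displacement curve
#'
#' The displacement curve is the concentration-form logistic with Hill
#' slope 1, `Y(c) = bottom + (top - bottom) / (1 + c / EC50)`, with
#' EC50 = Ki (1 + \[probe\]/Kd) (Cheng-Prusoff).  Noise is multiplicative
#' Gaussian as in [simulate_titration()].
#'
#' @param ki ground-truth competitor dissociation constant (uM, > 0).
#' @param kd_probe probe dissociation constant (uM, > 0).
#' @param radioligand_conc fixed probe concentration (uM, > 0).
#' @param top,bottom fluorescence plateaus (counts/s, top > bottom >= 0).
#' @param concentrations competitor concentrations (uM); default is the
#'   twelve-point 0-32 uM design used in the motivating assay.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates replicates per concentration.
#' @param ph_label condition label.
#' @param seed RNG seed.
#' @return A [titration_series()] with `radioligand_conc` recorded.
#' @export
simulate_competition <- function(ki, kd_probe, radioligand_conc = 5,
                                 top = 1e6, bottom = 0,
                                 concentrations = c(0, 2, 4, 6, 8, 10, 12, 14,
                                                    20, 24, 28, 32),
                                 noise_cv = 0.02, n_replicates = 3L,
                                 ph_label = "", seed = 1L) {
  if (ki <= 0 || kd_probe <= 0 || radioligand_conc < 0)
    .stopf("ki, kd_probe must be > 0 and radioligand_conc >= 0")
  if (!(top > bottom) || bottom < 0) .stopf("need top > bottom >= 0")
  rng <- .seeded_rng(seed)
  ec50 <- ki * (1 + radioligand_conc / kd_probe)
  conc <- rep(concentrations, each = n_replicates)
  y <- bottom + (top - bottom) / (1 + conc / ec50)
  y <- pmax(0, y * (1 + rng$rnorm(length(y), 0, noise_cv)))
  titration_series(conc, y, replicate = rep(seq_len(n_replicates),
                                            times = length(concentrations)),
                   ph_label = ph_label, radioligand_conc = radioligand_conc)
}

#' Materialise a complete demo dataset directory
#'
#' Writes every input the pipeline consumes: a toy complex PDB and
#' topology CSV, a multi-MODEL trajectory PDB per condition, saturation
#' and competition titration CSVs per condition, and a copy of the bundled
#' pKa prediction table.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed for all generated data.
#' @return Named character vector of the files written, invisibly.
#' @export
write_demo_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  sys <- make_toy_complex(toy_complex_spec(seed = seed))
  write_pdb(sys, p("complex.pdb"))
  write_topology(sys, p("topology.csv"))

  loose <- seq(1, 4)
  tr_hi <- simulate_trajectory(sys, fluctuation_spec(
    n_frames = 100L, sigma_core = 0.3, sigma_loose = 0.3, seed = seed + 1L))
  tr_lo <- simulate_trajectory(sys, fluctuation_spec(
    n_frames = 100L, sigma_core = 0.3, sigma_loose = 0.9,
    loose_selection = loose, seed = seed + 2L))
  write_pdb(tr_hi, p("traj_pH7.4.pdb"))
  write_pdb(tr_lo, p("traj_pH5.5.pdb"))

  sat74 <- simulate_titration(kd = 2.33, bmax = 1e6, ph_label = "pH 7.4",
                              seed = seed + 3L)
  sat55 <- simulate_titration(kd = 4.83, bmax = 1e6, ph_label = "pH 5.5",
                              seed = seed + 4L)
  write_titration_csv(sat74, p("saturation_pH7.4.csv"), "pH 7.4")
  write_titration_csv(sat55, p("saturation_pH5.5.csv"), "pH 5.5")
  cmp74 <- simulate_competition(ki = 0.72, kd_probe = 2.33,
                                ph_label = "pH 7.4", seed = seed + 5L)
  cmp55 <- simulate_competition(ki = 1.24, kd_probe = 4.83,
                                ph_label = "pH 5.5", seed = seed + 6L)
  write_titration_csv(cmp74, p("competition_pH7.4.csv"), "pH 7.4")
  write_titration_csv(cmp55, p("competition_pH5.5.csv"), "pH 5.5")

  file.copy(system.file("extdata", "solg21_pka_predictions.csv",
                        package = "phbind"),
            p("pka_predictions.csv"), overwrite = TRUE)
  files <- list.files(dir, full.names = TRUE)
  invisible(stats::setNames(files, basename(files)))
}

## Local RNG wrapper: every generator draws from its own stream so
## generators are pure functions of (arguments, seed) and never disturb
## the caller's RNG state.
.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(rnorm = draw(stats::rnorm), runif = draw(stats::runif))
}
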