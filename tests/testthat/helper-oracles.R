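# Independent reference implementations used to cross-check the package's
# kernels, plus small fixture builders.  These deliberately use the most
# naive formulation available (double loops, grid searches, direct
# formulae) and never call the code paths they validate.

# O(N^2) double-loop receptor-ligand energy, scalar arithmetic only
naive_interaction_energy <- function(xyz, system) {
  a <- system$atoms
  ele <- 0; vdw <- 0
  for (i in system$receptor) {
    for (j in system$ligand) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      ele <- ele + 332.0636 * a$charge[i] * a$charge[j] / r
      eij <- sqrt(a$epsilon[i] * a$epsilon[j])
      if (eij > 0) {
        rm <- a$rmin_half[i] + a$rmin_half[j]
        vdw <- vdw + eij * ((rm / r)^12 - 2 * (rm / r)^6)
      }
    }
  }
  c(ele = ele, vdw = vdw, total = ele + vdw)
}

# brute-force rigid superposition: grid over Euler angles in a window
# around the identity (valid when the optimum is a small rotation),
# translation removed by centroid matching; the 1-degree sweep is refined
# twice around the running optimum (0.1 then 0.01 degrees)
grid_search_rmsd <- function(mobile, reference, window_deg = 10) {
  rot <- function(ax, ay, az) {
    ca <- cos(ax); sa <- sin(ax); cb <- cos(ay); sb <- sin(ay)
    cc <- cos(az); sc <- sin(az)
    Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
    Rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
  }
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  sweep_grid <- function(center, half_width, step) {
    best <- c(Inf, center)
    grid <- seq(-half_width, half_width, by = step)
    for (ax in center[1] + grid) for (ay in center[2] + grid)
      for (az in center[3] + grid) {
        fit <- A %*% t(rot(ax, ay, az))
        rmsd <- sqrt(mean(rowSums((fit - B)^2)))
        if (rmsd < best[1]) best <- c(rmsd, ax, ay, az)
      }
    best
  }
  d2r <- pi / 180
  b <- sweep_grid(c(0, 0, 0), window_deg * d2r, 1 * d2r)
  b <- sweep_grid(b[2:4], 1 * d2r, 0.1 * d2r)
  b <- sweep_grid(b[2:4], 0.1 * d2r, 0.01 * d2r)
  b[1]
}

# minimal hand-built system: n point atoms with explicit parameters
point_system <- function(xyz, charge = 0, epsilon = 0, rmin_half = 1.5,
                         radius = 1.7, mass = 12, receptor = NULL,
                         ligand = NULL, resnum = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  rep_n <- function(v) if (length(v) == 1L) rep(v, n) else v
  atoms <- data.frame(
    serial = seq_len(n), name = paste0("X", seq_len(n)), element = "C",
    resname = "UNK", resnum = resnum %||% seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_n(charge), epsilon = rep_n(epsilon),
    rmin_half = rep_n(rmin_half), radius = rep_n(radius),
    mass = rep_n(mass), stringsAsFactors = FALSE)
  molecular_system(atoms, receptor = receptor %||% seq_len(n),
                   ligand = ligand %||% integer(0))
}

# energy series wrapper around an arbitrary numeric vector
raw_energy_series <- function(values, temperature = 300) {
  phbind:::new_energy_series(ele = values, vdw = rep(0, length(values)),
                             times = seq_along(values) - 1,
                             temperature = temperature)
}

# random proper rotation matrix (via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# probe atom at the origin surrounded by a centro-symmetric scaffold
# (+/- pairs): superposing onto the time average leaves an oscillation of
# the probe untouched up to the exact 1/n translation share, with zero
# net torque, so two-state closed forms hold exactly
balanced_probe_system <- function(n_pairs = 10, radius = 10, seed = 1) {
  set.seed(seed)
  half <- matrix(rnorm(n_pairs * 3), n_pairs, 3)
  half <- half / sqrt(rowSums(half^2)) * radius
  base <- rbind(c(0, 0, 0), half, -half)
  list(system = point_system(base, resnum = seq_len(nrow(base))),
       base = base)
}

demo_pka_table <- function() {
  read_pka_csv(system.file("extdata", "solg21_pka_predictions.csv",
                           package = "phbind"))
}
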