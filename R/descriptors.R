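#' Kabsch superposition
#'
#' Weighted least-squares rigid superposition of `mobile` onto
#' `reference` via singular value decomposition, with the sign of the
#' smallest singular value corrected so only proper rotations
#' (det = +1) are returned.
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom), n >= 3.
#' @param weights optional per-atom weights (default uniform).
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `coords %*% rotation + translation`), `rmsd` (weighted
#'   post-fit RMSD, Angstrom) and `fitted` (transformed mobile
#'   coordinates).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3)
    .stopf("mobile and reference must be n x 3 matrices of equal size")
  n <- nrow(mobile)
  if (n < 3) .stopf("superposition needs >= 3 atoms")
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0) || sum(w) == 0)
    .stopf("weights must be non-negative with positive sum")
  w <- w / sum(w)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  fitted <- A %*% R
  fitted <- sweep(fitted, 2, cr, `+`)
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(rotation = R, translation = cr - as.vector(cm %*% R),
       rmsd = rmsd, fitted = fitted)
}

#' Per-frame backbone RMSD series
#'
#' Kabsch-superposes every frame onto the reference (the first frame by
#' default) over the backbone selection (N, CA, C) and reports the
#' post-fit RMSD in Angstrom.
#'
#' @param traj a [trajectory()].
#' @param selection atom indices to superpose and measure; default
#'   [select_backbone()] of the receptor.
#' @param reference reference coordinates for the selection (n_sel x 3);
#'   default: first frame.
#' @return A `descriptor_series` (list with `metric = "rmsd"`, `unit`,
#'   `values`, `times`, `mean`, `min`, `max`, `selection`).
#' @export
rmsd_series <- function(traj, selection = NULL, reference = NULL) {
  sel <- selection %||% select_backbone(traj$system)
  if (!length(sel)) .stopf("empty atom selection")
  ref <- reference %||% traj$frames[[1L]][sel, , drop = FALSE]
  vals <- vapply(traj$frames, function(f)
    kabsch_superpose(f[sel, , drop = FALSE], ref)$rmsd, numeric(1))
  .descriptor_series("rmsd", "A", vals, traj$times,
                     sprintf("%d atoms", length(sel)))
}

#' Per-residue RMSF profile
#'
#' Two-pass procedure: frames are first superposed (over the selection)
#' onto the first frame, the time-average structure is computed, frames
#' are re-superposed onto that average, and the fluctuation
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` is reported per residue in
#' Angstrom.  The selection defaults to one C-alpha per receptor residue.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @param selection atom indices (default [select_calpha()]).
#' @return An `rmsf_profile`: data.frame with columns `resnum`, `rmsf`
#'   plus attributes `selection` and `reference` (= "time-average").
#' @export
rmsf_profile <- function(traj, selection = NULL) {
  if (n_frames(traj) < 2) .stopf("RMSF needs >= 2 frames")
  sel <- selection %||% select_calpha(traj$system)
  if (!length(sel)) .stopf("empty atom selection")
  sub <- lapply(traj$frames, function(f) f[sel, , drop = FALSE])

  fit_to <- function(frames, ref) lapply(frames, function(f)
    kabsch_superpose(f, ref)$fitted)
  pass1 <- fit_to(sub, sub[[1L]])
  avg1 <- Reduce(`+`, pass1) / length(pass1)
  pass2 <- fit_to(sub, avg1)
  avg2 <- Reduce(`+`, pass2) / length(pass2)

  dev2 <- Reduce(`+`, lapply(pass2, function(f) rowSums((f - avg2)^2))) /
    length(pass2)
  out <- data.frame(resnum = traj$system$atoms$resnum[sel],
                    rmsf = sqrt(dev2))
  class(out) <- c("rmsf_profile", "data.frame")
  attr(out, "selection") <- sprintf("%d atoms", length(sel))
  attr(out, "reference") <- "time-average"
  out
}

#' Radius of gyration series
#'
#' `Rg = sqrt( sum m_i |r_i - r_cm|^2 / sum m_i )` per frame, reported in
#' nm (coordinates are kept in Angstrom internally; the nm conversion
#' happens only here, at the reporting boundary).
#'
#' @param traj a [trajectory()].
#' @param selection atom indices (default: all atoms).
#' @param mass_weighted use atomic masses (default TRUE); otherwise
#'   uniform weights.
#' @return A `descriptor_series` with `metric = "rg"` in nm.
#' @export
radius_of_gyration <- function(traj, selection = NULL, mass_weighted = TRUE) {
  sel <- selection %||% seq_len(n_atoms(traj))
  if (!length(sel)) .stopf("empty atom selection")
  m <- if (mass_weighted) traj$system$atoms$mass[sel] else rep(1, length(sel))
  if (sum(m) <= 0) .stopf("total mass must be > 0")
  w <- m / sum(m)
  vals <- vapply(traj$frames, function(f) {
    x <- f[sel, , drop = FALSE]
    cm <- colSums(x * w)
    sqrt(sum(w * rowSums(sweep(x, 2, cm)^2))) / 10  # A -> nm
  }, numeric(1))
  .descriptor_series("rg", "nm", vals, traj$times,
                     sprintf("%d atoms%s", length(sel),
                             if (mass_weighted) ", mass-weighted" else ""))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places `n_sphere_points` test points on a deterministic Fibonacci
#' lattice on each atom's expanded sphere (radius + probe); a point is
#' exposed when it lies outside every other atom's expanded sphere.
#' Per-atom SASA is `4 pi (r + probe)^2` times the exposed fraction,
#' reported in nm^2.  Exactly coincident spheres share their boundary
#' points deterministically by atom and point index, so two fully
#' overlapping identical atoms jointly report one sphere's area.
#'
#' @param x coordinates (n x 3 matrix, Angstrom) or a `molecular_system`.
#' @param radii per-atom radii (Angstrom); taken from the system when `x`
#'   is one.  Defaults to element radii C 1.70, N 1.55, O 1.52, S 1.80,
#'   H 1.20.
#' @param probe_radius probe radius (Angstrom, default 1.4).
#' @param n_sphere_points lattice points per atom (>= 100, default 960).
#' @return list with `total` (nm^2) and `per_atom` (nm^2 vector).
#' @export
sasa <- function(x, radii = NULL, probe_radius = 1.4, n_sphere_points = 960L) {
  if (inherits(x, "molecular_system")) {
    radii <- radii %||% x$atoms$radius
    x <- coords(x)
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(radii)) .stopf("radii are required for bare coordinates")
  if (length(radii) == 1L) radii <- rep(radii, n)
  if (any(radii <= 0)) .stopf("radii must be > 0")
  if (n_sphere_points < 100) .stopf("need >= 100 sphere points")

  lattice <- .fibonacci_sphere(n_sphere_points)
  R <- radii + probe_radius
  tol <- 1e-9
  per_atom <- numeric(n)
  cdist <- as.matrix(stats::dist(x))
  for (i in seq_len(n)) {
    pts <- sweep(lattice * R[i], 2, x[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    tied <- vector("list", n_sphere_points)
    ## only neighbours whose expanded sphere can reach atom i's surface
    nbr <- which(cdist[i, ] < R[i] + R + tol & seq_len(n) != i)
    for (j in nbr) {
      d2 <- rowSums(sweep(pts, 2, x[j, ])^2)
      strict <- d2 < (R[j] - tol)^2
      exposed[strict] <- FALSE
      on_boundary <- !strict & abs(sqrt(d2) - R[j]) <= tol
      for (k in which(on_boundary)) tied[[k]] <- c(tied[[k]], j)
    }
    has_tie <- exposed & lengths(tied) > 0
    for (k in which(has_tie)) {
      owners <- sort(c(i, tied[[k]]))
      if (owners[1L + (k - 1L) %% length(owners)] != i) exposed[k] <- FALSE
    }
    per_atom[i] <- 4 * pi * R[i]^2 * mean(exposed) / 100  # A^2 -> nm^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' SASA over a trajectory
#'
#' Applies [sasa()] per frame.
#'
#' @inheritParams sasa
#' @param traj a [trajectory()].
#' @param selection atom indices (default all).
#' @return A `descriptor_series` with `metric = "sasa"` in nm^2.
#' @export
sasa_series <- function(traj, selection = NULL, probe_radius = 1.4,
                        n_sphere_points = 960L) {
  sel <- selection %||% seq_len(n_atoms(traj))
  radii <- traj$system$atoms$radius[sel]
  vals <- vapply(traj$frames, function(f)
    sasa(f[sel, , drop = FALSE], radii, probe_radius, n_sphere_points)$total,
    numeric(1))
  .descriptor_series("sasa", "nm^2", vals, traj$times,
                     sprintf("%d atoms", length(sel)))
}

## deterministic Fibonacci lattice on the unit sphere (no RNG)
.fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.descriptor_series <- function(metric, unit, values, times, selection) {
  structure(list(metric = metric, unit = unit, values = values,
                 times = times, mean = mean(values), min = min(values),
                 max = max(values), selection = selection),
            class = "descriptor_series")
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat(sprintf("%s series (%s, %s): %d frames, mean %.2f, range [%.2f, %.2f]\n",
              toupper(x$metric), x$unit, x$selection, length(x$values),
              x$mean, x$min, x$max))
  invisible(x)
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("RMSF profile (A, %s, reference: %s): %d residues, mean %.2f\n",
              attr(x, "selection"), attr(x, "reference"), nrow(x),
              mean(x$rmsf)))
  invisible(x)
}

#' @export
plot.descriptor_series <- function(x, ...) {
  plot(x$times, x$values, type = "l", xlab = "time (ns)",
       ylab = sprintf("%s (%s)", toupper(x$metric), x$unit), ...)
  invisible(x)
}

#' @export
plot.rmsf_profile <- function(x, ...) {
  plot(x$resnum, x$rmsf, type = "h", xlab = "residue",
       ylab = "RMSF (A)", ...)
  invisible(x)
}
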