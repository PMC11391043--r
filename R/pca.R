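#' Cartesian principal component analysis of C-alpha coordinates
#'
#' Frames are Kabsch-superposed onto the time-average structure (the
#' average is iterated twice), the selected C-alpha coordinates are
#' flattened to a frames x (3 n_CA) matrix, and the covariance is
#' eigendecomposed.  Projections of each frame onto the leading
#' components are reported in nm; eigenvalues in nm^2.  Sign convention:
#' each component's largest-magnitude coefficient is made positive, so
#' results are reproducible across platforms.
#'
#' @param traj a [trajectory()] with >= 3 frames.
#' @param selection atom indices (default [select_calpha()], >= 2 atoms).
#' @param n_components components to report projections for (default 2;
#'   the full spectrum of eigenvalues is always returned).
#' @return An object of class `pca_result`: `components` (3n x k
#'   orthonormal matrix), `eigenvalues` (nm^2, all, non-increasing),
#'   `projections` (frames x k, nm), `explained_fraction`, `times`,
#'   `selection`.
#' @export
cartesian_pca <- function(traj, selection = NULL, n_components = 2L) {
  if (n_frames(traj) < 3) .stopf("PCA needs >= 3 frames")
  sel <- selection %||% select_calpha(traj$system)
  if (length(sel) < 2) .stopf("PCA needs >= 2 selected atoms")
  sub <- lapply(traj$frames, function(f) f[sel, , drop = FALSE])

  ## two-pass superposition onto the time-average structure
  fit_to <- function(frames, ref) lapply(frames, function(f)
    kabsch_superpose(f, ref)$fitted)
  pass1 <- fit_to(sub, sub[[1L]])
  avg <- Reduce(`+`, pass1) / length(pass1)
  pass2 <- fit_to(sub, avg)
  avg <- Reduce(`+`, pass2) / length(pass2)

  X <- do.call(rbind, lapply(pass2, function(f) as.vector(t(f)))) / 10  # nm
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  k <- min(n_components, ncol(pc$rotation))
  V <- pc$rotation[, seq_len(k), drop = FALSE]
  ## deterministic sign: largest-|coefficient| positive per component
  for (c_i in seq_len(k)) {
    peak <- which.max(abs(V[, c_i]))
    if (V[peak, c_i] < 0) V[, c_i] <- -V[, c_i]
  }
  proj <- Xc %*% V
  colnames(proj) <- paste0("PC", seq_len(k))
  structure(
    list(components = V, eigenvalues = eig,
         projections = proj,
         explained_fraction = eig / sum(eig),
         center = mu, times = traj$times,
         selection = sprintf("%d atoms", length(sel)),
         units = list(projections = "nm", eigenvalues = "nm^2")),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$projections)
  cat(sprintf("Cartesian PCA (%s): %d frames, %d components retained\n",
              x$selection, nrow(x$projections), k))
  for (i in seq_len(k))
    cat(sprintf("  PC%d: eigenvalue %.4g nm^2 (%.1f%% of variance)\n",
                i, x$eigenvalues[i], 100 * x$explained_fraction[i]))
  invisible(x)
}

#' @export
plot.pca_result <- function(x, ...) {
  plot(x$projections[, 1], x$projections[, 2],
       xlab = "PC1 (nm)", ylab = "PC2 (nm)",
       col = grDevices::gray(0.8 * (1 - seq_len(nrow(x$projections)) /
                                      nrow(x$projections))), pch = 4, ...)
  invisible(x)
}

#' Conformational spread of PCA scores
#'
#' Per-axis score ranges and a cluster-compactness scalar: the mean
#' Euclidean distance of the (PC1, PC2) scores to their medoid (the
#' frame minimising the summed distance to all others).  Lower
#' compactness = more localised clustering; a destabilised condition
#' shows a larger value.
#'
#' @param result a `pca_result`.
#' @return list with `ranges` (k x 2 matrix of min/max per component)
#'   and `compactness` (nm).
#' @export
spread_metrics <- function(result) {
  if (!inherits(result, "pca_result")) .stopf("result must be a pca_result")
  P <- result$projections[, seq_len(min(2L, ncol(result$projections))),
                          drop = FALSE]
  ranges <- t(apply(result$projections, 2, range))
  colnames(ranges) <- c("min", "max")
  D <- as.matrix(stats::dist(P))
  medoid <- which.min(colSums(D))
  list(ranges = ranges, compactness = mean(D[, medoid]), medoid = medoid)
}
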