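#' Fit a one-site saturation binding model
#'
#' Fits fluorescence saturation data to `Y = Bmax X / (Kd + X)` by
#' Levenberg-Marquardt nonlinear least squares, where X is the probe
#' concentration (uM) and Y the fluorescence intensity (counts/s).  The
#' Scatchard linearisation (bound/free against bound; slope = -1/Kd) is
#' computed as a diagnostic from the same data: the nonlinear estimate is
#' primary because Scatchard regression is statistically biased, and a
#' discrepancy above 20% between the two Kd estimates raises a warning.
#'
#' @param series a [titration_series()].
#' @param use_means fit replicate means (default, matching how such curves
#'   are usually presented as mean +/- SEM) or all pooled points.
#' @return An object of class `saturation_fit` with components `kd`,
#'   `bmax` (uM, counts/s), `se_kd`, `se_bmax`, `r_squared`,
#'   `scatchard_slope` (1/uM), `scatchard_intercept`, `scatchard_kd`, and
#'   `fit` (Levenberg-Marquardt diagnostics: `par`, `se`, `vcov`,
#'   `deviance`, `niter`).  Methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot`.
#' @examples
#' s <- simulate_titration(kd = 2.33, bmax = 1e6, noise_cv = 0, seed = 1)
#' fit <- fit_saturation(s)
#' coef(fit)
#' @export
fit_saturation <- function(series, use_means = TRUE) {
  if (!inherits(series, "titration_series"))
    .stopf("series must be a titration_series")
  d <- .fit_data(series, use_means)
  if (length(unique(d$x)) < 4)
    .stopf("need >= 4 distinct concentrations")
  if (any(d$y < 0)) .stopf("intensities must be non-negative")
  if (all(d$y == 0)) .stopf("degenerate data: all intensities are zero")

  bmax0 <- max(d$y)
  half <- which(d$y >= bmax0 / 2)
  kd0 <- if (length(half)) max(d$x[half[1L]], 1e-6) else stats::median(d$x[d$x > 0])
  fit <- .lm_fit(function(p) d$y - p[["bmax"]] * d$x / (p[["kd"]] + d$x),
                 jac = function(p) cbind(
                   bmax = -d$x / (p[["kd"]] + d$x),
                   kd = p[["bmax"]] * d$x / (p[["kd"]] + d$x)^2),
                 start = c(bmax = bmax0, kd = kd0),
                 lower = c(bmax = 0, kd = 1e-12),
                 label = "saturation")
  est <- fit$par
  se <- fit$se
  yhat <- d$y - fit$residuals
  ss_tot <- sum((d$y - mean(d$y))^2)
  r2 <- if (ss_tot > 0) 1 - sum((d$y - yhat)^2) / ss_tot else 1

  ## Scatchard diagnostic: bound/free vs bound, X = 0 excluded (free
  ## approximated by total probe, valid when probe >> protein)
  sc <- d[d$x > 0, ]
  sc_fit <- stats::lm(I(y / x) ~ y, data = sc)
  sc_slope <- unname(stats::coef(sc_fit)[2L])
  sc_int <- unname(stats::coef(sc_fit)[1L])
  sc_kd <- if (sc_slope < 0) -1 / sc_slope else NA_real_
  if (is.finite(sc_kd) && abs(sc_kd - est[["kd"]]) / est[["kd"]] > 0.20)
    .warnf("Scatchard Kd (%.3g) deviates >20%% from nonlinear Kd (%.3g)",
           sc_kd, est[["kd"]])

  structure(
    list(kd = unname(est[["kd"]]), bmax = unname(est[["bmax"]]),
         se_kd = unname(se[["kd"]]), se_bmax = unname(se[["bmax"]]),
         r_squared = r2,
         scatchard_slope = sc_slope, scatchard_intercept = sc_int,
         scatchard_kd = sc_kd,
         fit = fit, data = d, ph_label = series$ph_label,
         use_means = use_means),
    class = "saturation_fit")
}

#' Fit a one-site competitive displacement model and derive Ki
#'
#' Fits `Y(c) = bottom + (top - bottom) / (1 + c / EC50)` (Hill slope 1)
#' to a displacement titration, then converts the fitted EC50 to the
#' competitor dissociation constant via the Cheng-Prusoff relation
#' `Ki = EC50 / (1 + [probe] / Kd_probe)` -- the concentration-space
#' equivalent of the log-form one-site-fit-Ki model.  The relation is
#' unit-invariant, so working in uM matches a formulation written in nM.
#'
#' @param series a [titration_series()]; its `radioligand_conc` is used
#'   unless `radioligand_conc` is given.
#' @param kd_probe probe dissociation constant (uM), from a prior
#'   [fit_saturation()].
#' @param radioligand_conc fixed probe concentration (uM).
#' @param use_means fit replicate means (default) or pooled points.
#' @return An object of class `competition_fit` with `ec50`, `ki` (uM),
#'   `top`, `bottom`, `se_ec50`, `se_ki`, `kd_probe`, `radioligand_conc`,
#'   a `nonmonotone` flag, and `fit` (Levenberg-Marquardt diagnostics).
#' @examples
#' s <- simulate_competition(ki = 0.72, kd_probe = 2.33, noise_cv = 0, seed = 1)
#' fit <- fit_competition(s, kd_probe = 2.33)
#' coef(fit)
#' @export
fit_competition <- function(series, kd_probe,
                            radioligand_conc = series$radioligand_conc,
                            use_means = TRUE) {
  if (!inherits(series, "titration_series"))
    .stopf("series must be a titration_series")
  if (is.na(radioligand_conc))
    .stopf("radioligand_conc is required for a competition fit")
  if (kd_probe <= 0) .stopf("kd_probe must be > 0")
  d <- .fit_data(series, use_means)

  top0 <- max(d$y)
  bottom0 <- min(d$y)
  mid <- (top0 + bottom0) / 2
  pos <- d[d$x > 0, ]
  ec0 <- pos$x[which.min(abs(pos$y - mid))]

  ## monotonicity check: displacement must not increase with competitor
  ct <- suppressWarnings(
    stats::cor.test(d$x, d$y, method = "spearman", alternative = "greater"))
  nonmono <- is.finite(ct$p.value) && ct$estimate > 0 && ct$p.value < 0.01
  if (nonmono)
    .warnf("displacement curve rises with competitor concentration (Spearman rho %.2f, p %.3g)",
           ct$estimate, ct$p.value)

  fit <- .lm_fit(function(p)
    d$y - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) / (1 + d$x / p[["ec50"]])),
    jac = function(p) {
      u <- p[["ec50"]] / (p[["ec50"]] + d$x)
      cbind(top = -u, bottom = -(1 - u),
            ec50 = -(p[["top"]] - p[["bottom"]]) * d$x / (p[["ec50"]] + d$x)^2)
    },
    start = c(top = top0, bottom = bottom0, ec50 = max(ec0, 1e-6)),
    label = "competition")
  if (fit$par[["ec50"]] <= 0)
    .stopf("competition fit converged to a non-positive EC50")
  est <- fit$par
  se <- fit$se
  cp <- 1 + radioligand_conc / kd_probe
  structure(
    list(ec50 = unname(est[["ec50"]]), ki = unname(est[["ec50"]]) / cp,
         top = unname(est[["top"]]), bottom = unname(est[["bottom"]]),
         se_ec50 = unname(se[["ec50"]]), se_ki = unname(se[["ec50"]]) / cp,
         kd_probe = kd_probe, radioligand_conc = radioligand_conc,
         nonmonotone = nonmono,
         fit = fit, data = d, ph_label = series$ph_label,
         use_means = use_means),
    class = "competition_fit")
}

#' Rank competitor affinities
#'
#' Orders a set of competition fits by ascending Ki (strongest binder
#' first); ties broken lexicographically by label.
#'
#' @param fits list of `competition_fit` objects.
#' @param labels character labels, one per fit.
#' @return data.frame with columns `label`, `ki_uM`, `se_ki`, `ec50_uM`,
#'   `rank`, ordered by affinity.
#' @export
rank_affinities <- function(fits, labels) {
  if (length(fits) < 1) .stopf("need at least one fit")
  if (length(labels) != length(fits)) .stopf("one label per fit required")
  ki <- vapply(fits, function(f) f$ki, numeric(1))
  o <- order(ki, labels)
  data.frame(label = labels[o],
             ki_uM = ki[o],
             se_ki = vapply(fits, function(f) f$se_ki, numeric(1))[o],
             ec50_uM = vapply(fits, function(f) f$ec50, numeric(1))[o],
             rank = seq_along(o),
             stringsAsFactors = FALSE)
}

## Levenberg-Marquardt wrapper: analytic residual function in, estimates,
## standard errors (from the J'J Hessian and residual variance) and
## convergence diagnostics out.  nls.lm is used directly rather than the
## nlsLM formula interface because the latter re-derives the gradient
## numerically with a step proportional to the parameter value, which
## breaks down when a plateau parameter converges to ~0 on clean data.
.lm_fit <- function(resid_fn, start, jac = NULL, lower = NULL, upper = NULL,
                    label = "nonlinear") {
  ctl <- minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10)
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac, lower = lower,
                       upper = upper, control = ctl),
    error = function(e) .stopf("%s fit failed: %s", label, conditionMessage(e)))
  if (!out$info %in% 1:4)
    .stopf("%s fit did not converge after %d iterations (%s); last iterate: %s",
           label, out$niter, out$message,
           paste(sprintf("%s=%.4g", names(out$par), unlist(out$par)),
                 collapse = ", "))
  par <- unlist(out$par)
  rdf <- length(out$fvec) - length(par)
  vcov <- tryCatch({
    ih <- chol2inv(chol(out$hessian))
    ih * (out$deviance / max(rdf, 1L))
  }, error = function(e) matrix(NA_real_, length(par), length(par)))
  se <- stats::setNames(sqrt(pmax(diag(vcov), 0)), names(par))
  list(par = par, se = se, vcov = vcov, residuals = out$fvec,
       deviance = out$deviance, niter = out$niter, message = out$message,
       df_residual = rdf)
}

.fit_data <- function(series, use_means) {
  d <- series$data
  if (use_means) {
    agg <- stats::aggregate(intensity ~ conc_uM, data = d, FUN = mean)
    data.frame(x = agg$conc_uM, y = agg$intensity)
  } else {
    data.frame(x = d$conc_uM, y = d$intensity)
  }
}

#' @export
coef.saturation_fit <- function(object, ...) {
  c(kd = object$kd, bmax = object$bmax)
}

#' @export
coef.competition_fit <- function(object, ...) {
  c(ki = object$ki, ec50 = object$ec50, top = object$top,
    bottom = object$bottom)
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("One-site saturation fit%s\n",
              if (nzchar(x$ph_label)) paste0(" [", x$ph_label, "]") else ""))
  cat(sprintf("  Kd   = %.4g +/- %.2g uM\n", x$kd, x$se_kd))
  cat(sprintf("  Bmax = %.4g +/- %.2g counts/s\n", x$bmax, x$se_bmax))
  cat(sprintf("  R^2  = %.4f;  Scatchard Kd = %.4g uM (slope %.4g /uM)\n",
              x$r_squared, x$scatchard_kd, x$scatchard_slope))
  invisible(x)
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("One-site competitive displacement fit%s\n",
              if (nzchar(x$ph_label)) paste0(" [", x$ph_label, "]") else ""))
  cat(sprintf("  EC50 = %.4g +/- %.2g uM\n", x$ec50, x$se_ec50))
  cat(sprintf("  Ki   = %.4g +/- %.2g uM (probe %.3g uM, probe Kd %.3g uM)\n",
              x$ki, x$se_ki, x$radioligand_conc, x$kd_probe))
  if (isTRUE(x$nonmonotone))
    cat("  warning: curve not monotonically decreasing\n")
  invisible(x)
}

#' @export
summary.saturation_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.binding_fit")
}

#' @export
summary.competition_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.binding_fit")
}

#' @export
print.summary.binding_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit$fit
  cat(sprintf("\nLevenberg-Marquardt: %d iterations, residual SS %.4g on %d df\n  %s\n",
              f$niter, f$deviance, f$df_residual, f$message))
  est <- cbind(Estimate = f$par, `Std. Error` = f$se)
  print(est)
  invisible(x)
}

#' @export
predict.saturation_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$conc_uM %||% newdata$x
  object$bmax * x / (object$kd + x)
}

#' @export
predict.competition_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$conc_uM %||% newdata$x
  object$bottom + (object$top - object$bottom) / (1 + x / object$ec50)
}

#' @export
residuals.saturation_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
residuals.competition_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
plot.saturation_fit <- function(x, ...) {
  plot(x$data$x, x$data$y, xlab = "probe concentration (uM)",
       ylab = "fluorescence (counts/s)",
       main = "One-site saturation binding", ...)
  xs <- seq(0, max(x$data$x), length.out = 200)
  graphics::lines(xs, x$bmax * xs / (x$kd + xs))
  invisible(x)
}

#' @export
plot.competition_fit <- function(x, ...) {
  plot(x$data$x, x$data$y, xlab = "competitor concentration (uM)",
       ylab = "fluorescence (counts/s)",
       main = "Competitive displacement", ...)
  xs <- seq(0, max(x$data$x), length.out = 200)
  graphics::lines(xs, x$bottom + (x$top - x$bottom) / (1 + xs / x$ec50))
  invisible(x)
}
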