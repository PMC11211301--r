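#' Recovery-curve model
#'
#' The sigmoidal recovery curve `f_RC(d) = 1 / (1 + (beta/d)^gamma)`:
#' `beta` is the diameter at which recovery reaches one half (same units as
#' `d`), `gamma` controls the steepness, and f tends to 1 for large
#' diameters. Diameters are fitted in centimetres throughout this package,
#' which places `beta` in the 1-3 cm range typical for Lu-177 SPECT.
#'
#' @param fit an `rc_fit` (or any list with `beta` and `gamma`).
#' @param d diameter(s), cm; must be positive.
#' @return recovery coefficient(s) in (0, 1).
#' @export
evaluate_fit <- function(fit, d) {
  if (any(d <= 0)) stop("diameter must be positive")
  1 / (1 + (fit$beta / d)^fit$gamma)
}

#' Partial-volume correction factor
#'
#' The reciprocal of the modelled recovery at the lesion diameter: measured
#' activity is divided by the theoretical RC of a sphere of the lesion's
#' size, i.e. multiplied by this factor.
#'
#' @inheritParams evaluate_fit
#' @return correction factor >= 1 for RC <= 1.
#' @export
pvc_factor <- function(fit, d) {
  rc <- evaluate_fit(fit, d)
  if (any(rc == 0)) stop("modelled RC is zero; correction undefined")
  1 / rc
}

#' Fit the recovery curve to per-sphere RCs
#'
#' Unweighted nonlinear least squares of `rc ~ 1/(1 + (beta/d)^gamma)`.
#' Initial values: `beta0` = diameter at which the linearly interpolated RC
#' crosses one half (median diameter if it never does), `gamma0 = 2`;
#' bounds `beta` in (0, 20] cm, `gamma` in (0, 10]. On non-convergence a
#' bounded multistart (L-BFGS-B over a small start grid) is used as
#' fallback. A flat response (zero RC variance) is flagged non-identifiable
#' rather than fitted.
#'
#' @param diameters sphere diameters (cm), at least 3, all positive.
#' @param rcs recovery coefficients, same length.
#' @return object of class `rc_fit`: `beta`, `gamma`, `r_squared`,
#'   `converged`, `identifiable`.
#' @export
fit_rc_curve <- function(diameters, rcs) {
  if (length(diameters) < 3 || length(rcs) != length(diameters))
    stop("need at least 3 (diameter, rc) pairs")
  if (any(diameters <= 0)) stop("diameters must be positive")
  if (stats::sd(rcs) == 0) {
    return(structure(list(beta = NA_real_, gamma = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          identifiable = FALSE),
                     class = "rc_fit"))
  }
  ord <- order(diameters)
  d <- diameters[ord]; rc <- rcs[ord]
  beta0 <- tryCatch(stats::approx(rc, d, xout = 0.5, ties = mean)$y,
                    error = function(e) NA_real_)
  if (!is.finite(beta0) || beta0 <= 0) beta0 <- stats::median(d)
  lower <- c(beta = 1e-6, gamma = 1e-6)
  upper <- c(beta = 20, gamma = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(rc ~ 1 / (1 + (beta / d)^gamma),
                      data = data.frame(d = d, rc = rc),
                      start = list(beta = beta0, gamma = 2),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    return(new_rc_fit(cf[["beta"]], cf[["gamma"]], d, rc, TRUE))
  }
  ## multistart fallback on the residual sum of squares
  ss <- function(p) sum((rc - 1 / (1 + (p[1] / d)^p[2]))^2)
  starts <- expand.grid(beta = c(0.5, 1, 2, 4) * beta0, gamma = c(1, 2, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(stats::optim(as.numeric(starts[i, ]), ss,
                               method = "L-BFGS-B",
                               lower = lower, upper = upper),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    return(structure(list(beta = NA_real_, gamma = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          identifiable = TRUE),
                     class = "rc_fit"))
  }
  new_rc_fit(best$par[1], best$par[2], d, rc, best$convergence == 0)
}

new_rc_fit <- function(beta, gamma, d, rc, converged) {
  pred <- 1 / (1 + (beta / d)^gamma)
  ss_res <- sum((rc - pred)^2)
  ss_tot <- sum((rc - mean(rc))^2)
  structure(list(beta = beta, gamma = gamma,
                 r_squared = 1 - ss_res / ss_tot,
                 converged = converged, identifiable = TRUE),
            class = "rc_fit")
}

#' @export
print.rc_fit <- function(x, ...) {
  cat(sprintf("rc_fit: beta = %.4g cm, gamma = %.4g, r^2 = %.4f%s\n",
              x$beta, x$gamma, x$r_squared,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Ensemble statistics of recovery-curve fits
#'
#' Across an ensemble of per-permutation fits: the mean curve
#' `mean_i f_i(d)`, the pointwise sample standard deviation (N-1
#' denominator), pointwise min/max envelopes, and summary statistics of the
#' fit parameters including the spread statistics
#' `theta_beta = (beta_max - beta_min)/mean(beta)` (and likewise for gamma).
#'
#' @param fits list of `rc_fit` objects (>= 2, all identifiable).
#' @param eval_diameters diameters (cm) at which the curve table is
#'   evaluated.
#' @return object of class `fit_ensemble`: functions `mean_curve(d)` and
#'   `sigma_curve(d)`, a `curve_table` at `eval_diameters` (mean, sd, min,
#'   max), and a `params` summary data.frame.
#' @export
ensemble_stats <- function(fits, eval_diameters) {
  fits <- Filter(function(f) isTRUE(f$identifiable), fits)
  if (length(fits) < 2) stop("need at least 2 fits")
  betas <- vapply(fits, `[[`, 0, "beta")
  gammas <- vapply(fits, `[[`, 0, "gamma")
  member_mat <- function(d)
    vapply(fits, evaluate_fit, numeric(length(d)), d = d)
  mean_curve <- function(d) rowMeans(matrix(member_mat(d), nrow = length(d)))
  sigma_curve <- function(d) {
    m <- matrix(member_mat(d), nrow = length(d))
    apply(m, 1, stats::sd)
  }
  m <- matrix(member_mat(eval_diameters), nrow = length(eval_diameters))
  curve_table <- data.frame(diameter = eval_diameters,
                            mean = rowMeans(m),
                            sd = apply(m, 1, stats::sd),
                            min = apply(m, 1, min),
                            max = apply(m, 1, max))
  params <- data.frame(
    parameter = c("beta", "gamma"),
    mean = c(mean(betas), mean(gammas)),
    sd = c(stats::sd(betas), stats::sd(gammas)),
    min = c(min(betas), min(gammas)),
    max = c(max(betas), max(gammas)))
  params$theta <- (params$max - params$min) / params$mean
  structure(list(n = length(fits), mean_curve = mean_curve,
                 sigma_curve = sigma_curve, curve_table = curve_table,
                 params = params,
                 r_squared = vapply(fits, `[[`, 0, "r_squared")),
            class = "fit_ensemble")
}
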