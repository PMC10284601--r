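#' Hill transformation of an oxygen-equilibrium series
#'
#' Maps each (PO2, S) point to Hill coordinates
#' `x = log10(PO2)`, `y = log10(S / (1 - S))`. On these coordinates a
#' two-parameter Hill saturation curve is the straight line
#' `y = n50 * (x - log10 P50)`.
#'
#' @param series an [oec_series()].
#' @return data frame with columns `log_po2`, `logit_sat`, one row per point,
#'   input order preserved.
#' @export
hill_transform <- function(series) {
  validate_oec_series(series)
  s <- series$saturation
  data.frame(log_po2 = log10(series$po2), logit_sat = log10(s / (1 - s)))
}

#' Fit a Hill plot: P50, n50 and their standard errors
#'
#' Ordinary least squares of `log10(S/(1-S))` on `log10(PO2)`. The slope is
#' the cooperativity coefficient `n50`; the x-intercept `-intercept/slope` is
#' `log10 P50`. `se_n50` is the regression slope SE; `se_log_p50` is
#' propagated from the full 2x2 coefficient covariance by a first-order
#' (delta-method) expansion of `-a/b`:
#' grad = (-1/b, a/b^2), `var = grad' V grad`.
#'
#' No weighting is applied: points are restricted by protocol to the 30--70%
#' saturation band, where the heteroscedasticity induced by the logit
#' transform is mild.
#'
#' @param series an [oec_series()] with at least 3 points and at least 2
#'   distinct oxygen tensions (replicate tensions are allowed).
#' @return an object of class `hill_fit` with fields `p50`, `log_p50`, `n50`,
#'   `se_log_p50`, `se_p50`, `se_n50`, `r2`, `n_points`, `dof`, `sample_id`,
#'   `condition`, `prenatal`.
#' @export
fit_hill <- function(series) {
  validate_oec_series(series)
  h <- hill_transform(series)
  if (length(unique(h$log_po2)) < 2) {
    stop("all oxygen tensions identical in series '", series$sample_id,
         "': Hill fit is rank-deficient")
  }
  fit <- stats::lm(logit_sat ~ log_po2, data = h)
  b <- unname(stats::coef(fit)[2]) # slope = n50
  a <- unname(stats::coef(fit)[1])
  if (!is.finite(b) || b <= 0) {
    stop("non-positive Hill slope in series '", series$sample_id,
         "': degenerate or non-cooperative data")
  }
  V <- quiet_perfect_fit(stats::vcov(fit))
  grad <- c(-1 / b, a / b^2)
  se_log_p50 <- sqrt(drop(t(grad) %*% V %*% grad))
  log_p50 <- -a / b
  p50 <- 10^log_p50
  if (log_p50 < min(h$log_po2) || log_p50 > max(h$log_po2)) {
    warning("P50 of series '", series$sample_id,
            "' lies outside the measured tension range (extrapolated)")
  }
  structure(
    list(
      sample_id = series$sample_id,
      condition = series$condition,
      prenatal = series$prenatal,
      p50 = p50,
      log_p50 = log_p50,
      n50 = b,
      se_log_p50 = se_log_p50,
      se_p50 = log(10) * p50 * se_log_p50,
      se_n50 = unname(sqrt(diag(V))[2]),
      r2 = quiet_perfect_fit(summary(fit)$r.squared),
      n_points = nrow(h),
      dof = nrow(h) - 2L
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> %s [%s, pH %.2f, %.1f C]\n  P50 = %.4g +/- %.2g mm Hg, n50 = %.4g +/- %.2g, r2 = %.5f (n = %d)\n",
    x$sample_id, x$condition$label, x$condition$ph,
    kelvin_to_celsius(x$condition$temperature),
    x$p50, x$se_p50, x$n50, x$se_n50, x$r2, x$n_points
  ))
  invisible(x)
}
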