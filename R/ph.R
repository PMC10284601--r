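#' Regress log10 P50 on pH within one condition
#'
#' Fits the linear model `log10(P50) ~ pH` to a set of Hill fits sharing one
#' effector condition and one temperature. The fitted line is used to
#' standardize P50 at a reference pH ([p50_at_ph()]) and its slope over the
#' Bohr window is the Bohr coefficient ([bohr_coefficient()]).
#'
#' @param fits list of [fit_hill()] objects, all with the same condition label
#'   and temperature, at two or more distinct pH values.
#' @param weight_by_se logical; if `TRUE`, weight each point by
#'   `1 / se_log_p50^2` (inverse-variance). Default `FALSE` (unweighted).
#' @return object of class `ph_regression`: `slope` (dlogP50/dpH),
#'   `intercept`, `se_slope`, `n_fits`, `ph_range`, `condition_label`,
#'   `temperature`, plus the underlying `lm` fit.
#' @export
fit_logp50_vs_ph <- function(fits, weight_by_se = FALSE) {
  stopifnot(length(fits) >= 2)
  lab <- vapply(fits, function(f) f$condition$label, character(1))
  tmp <- vapply(fits, function(f) f$condition$temperature, numeric(1))
  if (length(unique(lab)) != 1) {
    stop("mixed condition labels in pH regression: ",
         paste(unique(lab), collapse = ", "))
  }
  if (diff(range(tmp)) > 1e-9) {
    stop("mixed temperatures in pH regression; regress per temperature")
  }
  ph <- vapply(fits, function(f) f$condition$ph, numeric(1))
  y <- vapply(fits, function(f) f$log_p50, numeric(1))
  if (length(unique(ph)) < 2) {
    stop("at least 2 distinct pH values are required")
  }
  w <- NULL
  if (isTRUE(weight_by_se)) {
    se <- vapply(fits, function(f) f$se_log_p50, numeric(1))
    w <- 1 / pmax(se, 1e-12)^2
  }
  d <- data.frame(ph = ph, log_p50 = y)
  fit <- stats::lm(log_p50 ~ ph, data = d, weights = w)
  cf <- stats::coef(fit)
  structure(
    list(
      condition_label = lab[1],
      temperature = tmp[1],
      slope = unname(cf[2]),
      intercept = unname(cf[1]),
      se_slope = unname(sqrt(diag(quiet_perfect_fit(stats::vcov(fit))))[2]),
      n_fits = length(fits),
      ph_range = range(ph),
      fit = fit
    ),
    class = "ph_regression"
  )
}

#' Standard error of the regression estimate at a given pH
#'
#' @param reg a `ph_regression`.
#' @param ph pH value(s) at which the SE of the fitted mean is wanted.
#' @return numeric vector of prediction SEs on the log10 P50 scale.
#' @export
se_pred <- function(reg, ph) {
  stopifnot(inherits(reg, "ph_regression"))
  stats::predict(reg$fit, newdata = data.frame(ph = ph), se.fit = TRUE)$se.fit
}

#' Interpolate P50 at a reference pH
#'
#' Evaluates the pH regression at `ph_ref` and back-transforms:
#' `P50 = 10^(slope * ph_ref + intercept)`. The SE on the mm Hg scale follows
#' from the log10 link to first order: `se_p50 = ln(10) * P50 * se_pred`.
#' Standardization more than 0.5 pH units outside the fitted range triggers an
#' extrapolation warning (not an error).
#'
#' @param reg a `ph_regression` from [fit_logp50_vs_ph()].
#' @param ph_ref reference pH (7.20 for adult hemoglobins, 7.10 for prenatal
#'   isoforms).
#' @return list with `p50`, `se_p50`, `log_p50`, `se_log_p50`, `ph_ref`.
#' @export
p50_at_ph <- function(reg, ph_ref) {
  stopifnot(inherits(reg, "ph_regression"), is.numeric(ph_ref),
            length(ph_ref) == 1)
  if (ph_ref < reg$ph_range[1] - 0.5 || ph_ref > reg$ph_range[2] + 0.5) {
    warning(sprintf(
      "reference pH %.2f is > 0.5 units outside the fitted range [%.2f, %.2f]",
      ph_ref, reg$ph_range[1], reg$ph_range[2]
    ))
  }
  log_p50 <- reg$slope * ph_ref + reg$intercept
  se_log <- unname(se_pred(reg, ph_ref))
  p50 <- 10^log_p50
  list(p50 = p50, se_p50 = log(10) * p50 * se_log,
       log_p50 = log_p50, se_log_p50 = se_log, ph_ref = ph_ref)
}

#' Bohr coefficient
#'
#' The Bohr effect is quantified as the slope `dlogP50/dpH` of the line fitted
#' to Hill-fit log10 P50 values whose pH lies inside the Bohr window
#' (inclusive endpoints; default 6.9--7.8). Points outside the window are
#' excluded before fitting and their count is reported.
#'
#' @param fits list of [fit_hill()] objects (one condition, one temperature).
#' @param window inclusive pH window, default `c(6.9, 7.8)`.
#' @return list with `phi` (slope, dlogP50/dpH), `se`, `n_used`, `n_excluded`,
#'   `window`, `condition_label`, `temperature`.
#' @export
bohr_coefficient <- function(fits, window = c(6.9, 7.8)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  ph <- vapply(fits, function(f) f$condition$ph, numeric(1))
  keep <- ph >= window[1] & ph <= window[2]
  if (sum(keep) < 2 || length(unique(ph[keep])) < 2) {
    stop("need >= 2 distinct pH values inside the Bohr window [",
         window[1], ", ", window[2], "]")
  }
  reg <- fit_logp50_vs_ph(fits[keep])
  list(phi = reg$slope, se = reg$se_slope,
       n_used = sum(keep), n_excluded = sum(!keep), window = window,
       condition_label = reg$condition_label, temperature = reg$temperature)
}

#' @export
print.ph_regression <- function(x, ...) {
  cat(sprintf(
    "<ph_regression> %s at %.1f C: logP50 = %.4g %+.4g * pH (se_slope %.3g, n = %d, pH %.2f-%.2f)\n",
    x$condition_label, kelvin_to_celsius(x$temperature),
    x$intercept, x$slope, x$se_slope, x$n_fits, x$ph_range[1], x$ph_range[2]
  ))
  invisible(x)
}
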