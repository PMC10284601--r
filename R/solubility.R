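#' Percent hemoglobin precipitated at a given ammonium-sulfate molarity
#'
#' Precipitation is expressed relative to the sample's own 0 M control:
#' `100 * (1 - signal(M) / signal(0))`. When the requested molarity was not
#' measured exactly, the signal is linearly interpolated between the two
#' bracketing molarities. Small negative percentages (soluble signal above the
#' control, measurement noise) are clamped to 0 with a message.
#'
#' @param series a [solubility_series()].
#' @param molarity requested ammonium-sulfate molarity (default 3 M, the
#'   conventional comparison point).
#' @return percent precipitated in [0, 100].
#' @export
percent_precipitated <- function(series, molarity = 3) {
  validate_solubility_series(series)
  m <- series$ammonium_sulfate
  s <- series$soluble_signal
  control <- mean(s[m == 0])
  if (!is.finite(control) || control <= 0) {
    stop("0 M control signal must be positive for sample '",
         series$sample_id, "'")
  }
  if (molarity < min(m) || molarity > max(m)) {
    stop(sprintf(
      "molarity %.3g M outside measured range [%.3g, %.3g] for sample '%s'",
      molarity, min(m), max(m), series$sample_id
    ))
  }
  sig <- stats::approx(m, s, xout = molarity, ties = mean)$y
  pct <- 100 * (1 - sig / control)
  if (pct < 0) {
    message(sprintf(
      "sample '%s': %.2f%% at %.3g M clamped to 0 (signal above control)",
      series$sample_id, pct, molarity
    ))
    pct <- 0
  }
  pct
}

#' Fit a salting-out curve
#'
#' Two-parameter logistic least-squares fit of the soluble fraction
#' (signal normalized to the 0 M control) against molarity:
#' `fraction = 1 / (1 + exp((M - midpoint) / slope))`. The midpoint is the
#' molarity of half-precipitation (higher midpoint = more soluble protein);
#' the slope is the transition width in mol/L.
#'
#' A fitted midpoint beyond the highest measured molarity is flagged
#' `no_transition = TRUE` ("no transition observed"); a soluble fraction that
#' rises by more than 0.10 with increasing molarity triggers a monotonicity
#' warning.
#'
#' @param series a [solubility_series()] with at least 4 distinct molarities.
#' @return object of class `salting_out_fit`: `midpoint_molarity`, `slope`,
#'   `no_transition`, `curve` (data frame of molarity and percent
#'   precipitated), `percent_precipitated_at_3M` (NA when 3 M is outside the
#'   measured range), `sample_id`.
#' @export
fit_salting_out <- function(series) {
  validate_solubility_series(series)
  m <- series$ammonium_sulfate
  s <- series$soluble_signal
  if (length(unique(m)) < 4) {
    stop("salting-out fit needs >= 4 distinct molarities")
  }
  control <- mean(s[m == 0])
  if (control <= 0) stop("0 M control signal must be positive")
  frac <- s / control

  # gross non-monotonicity check on the molarity-averaged curve
  avg <- tapply(frac, m, mean)
  if (any(diff(avg) > 0.10)) {
    warning("soluble fraction rises by > 0.10 with molarity in sample '",
            series$sample_id, "': salting-out fit may be unreliable")
  }

  start_mid <- if (any(avg <= 0.5)) {
    as.numeric(names(avg)[which(avg <= 0.5)[1]])
  } else {
    max(m)
  }
  d <- data.frame(m = m, frac = frac)
  fit <- minpack.lm::nlsLM(
    frac ~ 1 / (1 + exp((m - mid) / sl)),
    data = d,
    start = list(mid = start_mid, sl = 0.2),
    lower = c(mid = 0, sl = 1e-4),
    upper = c(mid = 20, sl = 5),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  mid <- unname(cf["mid"])
  no_transition <- mid > max(m)
  if (no_transition) {
    message("sample '", series$sample_id,
            "': no salting-out transition observed up to ",
            format(max(m)), " M")
  }
  pct3 <- if (3 >= min(m) && 3 <= max(m)) {
    percent_precipitated(series, 3)
  } else {
    NA_real_
  }
  uniq_m <- sort(unique(m))
  structure(
    list(
      sample_id = series$sample_id,
      midpoint_molarity = mid,
      slope = unname(cf["sl"]),
      no_transition = no_transition,
      percent_precipitated_at_3M = pct3,
      curve = data.frame(
        molarity = uniq_m,
        percent_precipitated = vapply(
          uniq_m, function(x) percent_precipitated(series, x), numeric(1)
        )
      )
    ),
    class = "salting_out_fit"
  )
}

#' @export
print.salting_out_fit <- function(x, ...) {
  cat(sprintf(
    "<salting_out_fit> %s: midpoint %.3g M, slope %.3g M%s%s\n",
    x$sample_id, x$midpoint_molarity, x$slope,
    if (is.na(x$percent_precipitated_at_3M)) "" else
      sprintf(", %.1f%% precipitated at 3 M", x$percent_precipitated_at_3M),
    if (x$no_transition) " [no transition observed]" else ""
  ))
  invisible(x)
}
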