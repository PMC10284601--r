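#' Apparent enthalpy of oxygenation (van't Hoff isochore)
#'
#' From P50 measured at two absolute temperatures `t1 < t2`:
#' `dH = 2.303 * R * (log10 P50(t1) - log10 P50(t2)) / (1/t1 - 1/t2)`,
#' reported in kJ mol-1 O2. For a normal hemoglobin P50 rises with
#' temperature, so `dH < 0` (oxygenation is exothermic).
#'
#' @param p50_low_t P50 (mm Hg) at the lower temperature `t1`.
#' @param p50_high_t P50 (mm Hg) at the higher temperature `t2`.
#' @param t1,t2 absolute temperatures, kelvin, `t1 < t2`.
#' @param gas_constant R, J mol-1 K-1.
#' @return raw apparent enthalpy, kJ mol-1 O2.
#' @export
vant_hoff_dh <- function(p50_low_t, p50_high_t, t1, t2,
                         gas_constant = 8.314) {
  if (!is.finite(t1) || !is.finite(t2) || t1 <= 0 || t2 <= 0) {
    stop("temperatures must be positive kelvin values")
  }
  if (t1 == t2) stop("t1 and t2 must differ")
  if (t1 > t2) stop("t1 must be the lower temperature")
  if (any(c(p50_low_t, p50_high_t) <= 0) ||
      any(!is.finite(c(p50_low_t, p50_high_t)))) {
    stop("P50 values must be positive and finite")
  }
  dlog <- log10(p50_low_t) - log10(p50_high_t)
  2.303 * gas_constant * dlog / (1 / t1 - 1 / t2) / 1000
}

#' Correct a van't Hoff enthalpy for the heat of O2 solubilization
#'
#' Gas-tension-based P50 measurements fold the enthalpy of dissolving O2 in
#' the aqueous phase into the apparent oxygenation enthalpy; the corrected
#' value removes it: `dH' = dH_raw + 12.55` kJ mol-1 O2 by default (the
#' correction shifts the estimate toward less exothermic values). The constant
#' is configurable, including its sign.
#'
#' @param dh_raw raw van't Hoff enthalpy, kJ mol-1 O2.
#' @param correction_kj solubilization correction, kJ mol-1 O2 (default 12.55).
#' @return corrected enthalpy `dH'`, kJ mol-1 O2.
#' @export
correct_solubilization <- function(dh_raw, correction_kj = 12.55) {
  stopifnot(is.numeric(dh_raw), all(is.finite(dh_raw)))
  dh_raw + correction_kj
}

#' Thermal summary for one condition
#'
#' Standardizes log10 P50 at `ph_ref` for each of exactly two temperatures,
#' applies the van't Hoff isochore and the solubilization correction, and
#' propagates the SE from the two regression-prediction SEs:
#' `se_dh = |C| * sqrt(se1^2 + se2^2)` with
#' `C = 2.303 R / (1/t1 - 1/t2) / 1000`.
#'
#' @param regs_by_temp list of exactly two `ph_regression` objects for the
#'   same condition at two temperatures.
#' @param ph_ref reference pH for standardization.
#' @param config run configuration (gas constant and correction).
#' @return object of class `thermal_result`: `dh_raw`, `dh_corrected`,
#'   `se_dh` (kJ mol-1 O2), `t1`, `t2`, `p50_t1`, `p50_t2`, `ph_ref`,
#'   `condition_label`.
#' @export
thermal_summary <- function(regs_by_temp, ph_ref, config = default_config()) {
  if (length(regs_by_temp) != 2) {
    stop("thermal summary requires exactly two temperatures, got ",
         length(regs_by_temp))
  }
  labs <- vapply(regs_by_temp, function(r) r$condition_label, character(1))
  if (length(unique(labs)) != 1) {
    stop("thermal summary requires one condition, got: ",
         paste(unique(labs), collapse = ", "))
  }
  temps <- unname(vapply(regs_by_temp, function(r) r$temperature, numeric(1)))
  if (abs(diff(temps)) < 1e-9) stop("the two temperatures must differ")
  ord <- order(temps)
  regs_by_temp <- regs_by_temp[ord]
  t1 <- temps[ord][1]
  t2 <- temps[ord][2]
  a <- p50_at_ph(regs_by_temp[[1]], ph_ref)
  b <- p50_at_ph(regs_by_temp[[2]], ph_ref)
  dh_raw <- vant_hoff_dh(a$p50, b$p50, t1, t2,
                         gas_constant = config$gas_constant)
  cc <- 2.303 * config$gas_constant / (1 / t1 - 1 / t2) / 1000
  se_dh <- abs(cc) * sqrt(a$se_log_p50^2 + b$se_log_p50^2)
  structure(
    list(
      dh_raw = dh_raw,
      dh_corrected = correct_solubilization(
        dh_raw, config$solubilization_correction_kj
      ),
      se_dh = se_dh,
      t1 = t1, t2 = t2,
      p50_t1 = a$p50, p50_t2 = b$p50,
      ph_ref = ph_ref,
      condition_label = labs[1]
    ),
    class = "thermal_result"
  )
}

#' @export
print.thermal_result <- function(x, ...) {
  cat(sprintf(
    "<thermal_result> %s, pH %.2f, %.1f-%.1f C:\n  dH raw = %.2f, dH' = %.2f +/- %.2f kJ/mol O2\n",
    x$condition_label, x$ph_ref, kelvin_to_celsius(x$t1),
    kelvin_to_celsius(x$t2), x$dh_raw, x$dh_corrected, x$se_dh
  ))
  invisible(x)
}
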