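#' Experimental condition of one oxygen-equilibrium series
#'
#' A `hb_condition` records the chemical and thermal context of one
#' equilibrium series: pH, temperature, chloride (as KCl molarity),
#' 2,3-diphosphoglycerate (DPG) and heme concentration. DPG may be given
#' either as an absolute molarity or as a fold excess over tetrameric
#' hemoglobin; with four hemes per tetramer a fold excess `f` resolves to
#' `dpg = f * heme_conc / 4`.
#'
#' @param ph pH of the solution; accepted range 6.0--9.0.
#' @param temp_c temperature in degrees Celsius (the usual input unit).
#'   Exactly one of `temp_c`/`temp_k` must be given.
#' @param temp_k temperature in kelvin.
#' @param kcl KCl concentration, mol/L.
#' @param dpg DPG concentration, mol/L. Exactly one of `dpg`/`dpg_fold_excess`
#'   may be given; if neither, DPG is 0.
#' @param dpg_fold_excess DPG as fold molar excess over tetramer.
#' @param heme_conc heme concentration, mol heme/L (must be positive; the
#'   tetramer concentration is `heme_conc / 4`).
#' @param label free-text condition label; if `NULL`, derived from the
#'   effectors present ("stripped", "KCl", "DPG", "KCl+DPG").
#' @return an object of class `hb_condition`.
#' @examples
#' condition(ph = 7.2, temp_c = 37, kcl = 0.1,
#'           dpg_fold_excess = 2, heme_conc = 0.25e-3)
#' @export
condition <- function(ph, temp_c = NULL, temp_k = NULL, kcl = 0,
                      dpg = NULL, dpg_fold_excess = NULL,
                      heme_conc, label = NULL) {
  if (is.null(temp_k) == is.null(temp_c)) {
    stop("give exactly one of temp_c or temp_k")
  }
  temperature <- if (is.null(temp_k)) celsius_to_kelvin(temp_c) else temp_k
  if (!is.null(dpg) && !is.null(dpg_fold_excess)) {
    stop("give at most one of dpg (mol/L) or dpg_fold_excess")
  }
  if (is.null(dpg)) {
    dpg <- if (is.null(dpg_fold_excess)) 0 else dpg_fold_excess * heme_conc / 4
  }
  x <- structure(
    list(ph = ph, temperature = temperature, kcl = kcl, dpg = dpg,
         heme_conc = heme_conc,
         label = if (is.null(label)) effector_label(kcl, dpg) else label),
    class = "hb_condition"
  )
  validate_condition(x)
}

celsius_to_kelvin <- function(temp_c) temp_c + 273.15
kelvin_to_celsius <- function(temp_k) temp_k - 273.15

effector_label <- function(kcl, dpg) {
  if (kcl > 0 && dpg > 0) "KCl+DPG"
  else if (kcl > 0) "KCl"
  else if (dpg > 0) "DPG"
  else "stripped"
}

validate_condition <- function(x) {
  stopifnot(inherits(x, "hb_condition"))
  num1 <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v)
  if (!num1(x$ph) || x$ph < 6.0 || x$ph > 9.0) {
    stop("pH must be a single value in [6.0, 9.0], got ", format(x$ph))
  }
  if (!num1(x$temperature) || x$temperature <= 0) {
    stop("temperature must be positive (kelvin)")
  }
  if (!num1(x$kcl) || x$kcl < 0) stop("kcl must be >= 0 mol/L")
  if (!num1(x$dpg) || x$dpg < 0) stop("dpg must be >= 0 mol/L")
  if (!num1(x$heme_conc) || x$heme_conc <= 0) {
    stop("heme_conc must be > 0 mol heme/L")
  }
  x
}

#' @export
print.hb_condition <- function(x, ...) {
  cat(sprintf(
    "<condition> %s | pH %.2f, %.2f K (%.1f C), KCl %g M, DPG %g M, heme %g M\n",
    x$label, x$ph, x$temperature, kelvin_to_celsius(x$temperature),
    x$kcl, x$dpg, x$heme_conc
  ))
  invisible(x)
}

# conditions are equal for grouping purposes when every numeric field and the
# label agree to within formatting precision
condition_key <- function(cond) {
  paste(cond$label, signif(cond$ph, 10), signif(cond$temperature, 10),
        signif(cond$kcl, 10), signif(cond$dpg, 10),
        signif(cond$heme_conc, 10), sep = "|")
}

#' Oxygen-equilibrium series
#'
#' One tonometry series: (PO2, fractional saturation) points measured for one
#' hemoglobin sample under one [condition()]. The thin-film protocol
#' equilibrates each solution with three to five oxygen tensions chosen to
#' give saturations between 30 and 70%, so at least three points are required
#' and saturations must lie strictly inside (0, 1) (the Hill logit is
#' undefined at 0 and 1).
#'
#' @param sample_id sample identifier (character scalar).
#' @param condition a `hb_condition`.
#' @param po2 oxygen tensions, mm Hg (all positive).
#' @param saturation fractional saturations, strictly in (0, 1).
#' @param prenatal logical; prenatal isoform flag (selects reference pH 7.1 in
#'   the pipeline).
#' @return an object of class `oec_series`.
#' @export
oec_series <- function(sample_id, condition, po2, saturation,
                       prenatal = FALSE) {
  x <- structure(
    list(sample_id = as.character(sample_id), condition = condition,
         po2 = as.numeric(po2), saturation = as.numeric(saturation),
         prenatal = isTRUE(prenatal)),
    class = "oec_series"
  )
  validate_oec_series(x)
}

validate_oec_series <- function(x) {
  stopifnot(inherits(x, "oec_series"))
  validate_condition(x$condition)
  n <- length(x$po2)
  if (n < 3) {
    stop("series '", x$sample_id, "' has ", n,
         " points; at least 3 oxygen tensions are required")
  }
  if (length(x$saturation) != n) stop("po2 and saturation lengths differ")
  if (any(!is.finite(x$po2)) || any(x$po2 <= 0)) {
    stop("all po2 must be finite and > 0 mm Hg")
  }
  if (any(!is.finite(x$saturation)) ||
      any(x$saturation <= 0) || any(x$saturation >= 1)) {
    stop("all saturations must lie strictly in (0, 1)")
  }
  x
}

#' @export
print.oec_series <- function(x, ...) {
  cat(sprintf("<oec_series> %s (%d points%s)\n", x$sample_id,
              length(x$po2), if (x$prenatal) ", prenatal" else ""))
  print(x$condition)
  print(data.frame(po2_mmHg = x$po2, saturation = x$saturation),
        row.names = FALSE)
  invisible(x)
}

#' Ammonium-sulfate solubility series
#'
#' Soluble-hemoglobin signal (an absorbance-like value from Drabkin's assay)
#' measured after incubation at a ladder of ammonium-sulfate molarities from 0
#' up to at most 3.5 M. The 0 M row is the control against which precipitation
#' percentages are expressed, so it must be present. Rows are stored sorted by
#' molarity; duplicate molarities are retained as independent observations.
#'
#' @param sample_id sample identifier.
#' @param ammonium_sulfate molarities, mol/L, in [0, 3.5].
#' @param soluble_signal non-negative soluble-Hb signal at each molarity.
#' @return an object of class `solubility_series`.
#' @export
solubility_series <- function(sample_id, ammonium_sulfate, soluble_signal) {
  ord <- order(ammonium_sulfate)
  x <- structure(
    list(sample_id = as.character(sample_id),
         ammonium_sulfate = as.numeric(ammonium_sulfate)[ord],
         soluble_signal = as.numeric(soluble_signal)[ord]),
    class = "solubility_series"
  )
  validate_solubility_series(x)
}

validate_solubility_series <- function(x) {
  stopifnot(inherits(x, "solubility_series"))
  m <- x$ammonium_sulfate
  s <- x$soluble_signal
  if (length(m) != length(s)) stop("molarity and signal lengths differ")
  if (any(!is.finite(m)) || any(m < 0) || max(m) > 3.5) {
    stop("ammonium sulfate molarities must lie in [0, 3.5] M")
  }
  if (!any(m == 0)) {
    stop("solubility series '", x$sample_id, "' lacks the 0 M control row")
  }
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("soluble signals must be non-negative")
  }
  x
}

#' @export
print.solubility_series <- function(x, ...) {
  cat(sprintf("<solubility_series> %s (%d molarities, 0-%.2f M)\n",
              x$sample_id, length(x$ammonium_sulfate),
              max(x$ammonium_sulfate)))
  invisible(x)
}
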