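#' Allosteric-effector effect on P50
#'
#' The effect of an effector (DPG, chloride, or both) is the difference of
#' pH-standardized log10 P50 between the effector condition and the stripped
#' condition at the same temperature:
#' `delta = logP50(effector, ph_ref) - logP50(stripped, ph_ref)`.
#' Positive values mean the effector lowers O2 affinity. SEs of the two
#' standardized estimates are combined assuming independence:
#' `se = sqrt(se_effector^2 + se_stripped^2)`.
#'
#' @param reg_effector `ph_regression` for the effector condition.
#' @param reg_stripped `ph_regression` for the stripped condition.
#' @param ph_ref reference pH at which both regressions are evaluated.
#' @return list with `delta_log_p50`, `se`, `ph_ref`, `temperature`,
#'   `condition_label` (of the effector condition).
#' @export
effector_effect <- function(reg_effector, reg_stripped, ph_ref) {
  stopifnot(inherits(reg_effector, "ph_regression"),
            inherits(reg_stripped, "ph_regression"))
  if (abs(reg_effector$temperature - reg_stripped$temperature) > 1e-9) {
    stop("effector and stripped regressions are at different temperatures")
  }
  a <- p50_at_ph(reg_effector, ph_ref)
  b <- p50_at_ph(reg_stripped, ph_ref)
  list(
    delta_log_p50 = a$log_p50 - b$log_p50,
    se = sqrt(a$se_log_p50^2 + b$se_log_p50^2),
    ph_ref = ph_ref,
    temperature = reg_effector$temperature,
    condition_label = reg_effector$condition_label
  )
}

#' Summarize all effector effects for one hemoglobin
#'
#' Computes the DPG effect (condition "DPG" vs "stripped"), chloride effect
#' ("KCl" vs "stripped") and combined effect ("KCl+DPG" vs "stripped") from a
#' set of per-condition pH regressions at one temperature. Conditions that
#' were not measured yield absent (`NULL`) entries, never zeros.
#'
#' @param regs named list of `ph_regression` objects; names are condition
#'   labels and must include `"stripped"`.
#' @param ph_ref reference pH.
#' @return object of class `effector_effects` with fields `dpg_effect`,
#'   `cl_effect`, `combined_effect` (each a list as returned by
#'   [effector_effect()], or `NULL` if the condition is absent), `ph_ref`,
#'   `temperature`.
#' @export
summarize_effects <- function(regs, ph_ref) {
  if (!"stripped" %in% names(regs)) {
    stop("effector effects require a 'stripped' condition regression")
  }
  base <- regs[["stripped"]]
  eff <- function(label) {
    if (label %in% names(regs)) effector_effect(regs[[label]], base, ph_ref)
  }
  structure(
    list(
      dpg_effect = eff("DPG"),
      cl_effect = eff("KCl"),
      combined_effect = eff("KCl+DPG"),
      ph_ref = ph_ref,
      temperature = base$temperature
    ),
    class = "effector_effects"
  )
}

#' @export
print.effector_effects <- function(x, ...) {
  cat(sprintf("<effector_effects> at pH %.2f, %.1f C\n", x$ph_ref,
              kelvin_to_celsius(x$temperature)))
  show1 <- function(name, e) {
    if (is.null(e)) {
      cat(sprintf("  %-9s: (not measured)\n", name))
    } else {
      cat(sprintf("  %-9s: dlogP50 = %+.4f +/- %.4f\n", name,
                  e$delta_log_p50, e$se))
    }
  }
  show1("DPG", x$dpg_effect)
  show1("Cl-", x$cl_effect)
  show1("combined", x$combined_effect)
  invisible(x)
}
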