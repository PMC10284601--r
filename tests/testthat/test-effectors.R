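reg_through <- function(p50_at_72, slope = -0.4, tc = 37, label = "KCl+DPG") {
  # exact line with the given standardized P50 at pH 7.2
  b0 <- log10(p50_at_72) - slope * 7.2
  fits <- lapply(c(6.9, 7.2, 7.5, 7.8), function(ph) {
    fake_fit(ph, b0 + slope * ph, tc = tc, label = label)
  })
  fit_logp50_vs_ph(fits)
}

test_that("effector effect is the standardized log P50 difference", {
  # identical regressions: zero effect
  a <- reg_through(10.9)
  b <- reg_through(10.9, label = "stripped")
  expect_equal(effector_effect(a, b, 7.2)$delta_log_p50, 0, tolerance = 1e-12)

  # standardized pair (10.9, 5.4) mm Hg: delta = log10(10.9) - log10(5.4)
  e <- effector_effect(reg_through(10.9), reg_through(5.4, label = "stripped"),
                       7.2)
  expect_equal(e$delta_log_p50, log10(10.9 / 5.4), tolerance = 1e-12)
  expect_equal(e$delta_log_p50, 0.305, tolerance = 5e-4)

  # antisymmetry
  e_rev <- effector_effect(reg_through(5.4, label = "stripped"),
                           reg_through(10.9), 7.2)
  expect_equal(e_rev$delta_log_p50, -e$delta_log_p50, tolerance = 1e-12)

  # independent-error SE combination
  expect_equal(e$se, sqrt(se_pred(reg_through(10.9), 7.2)^2 +
                            se_pred(reg_through(5.4), 7.2)^2),
               tolerance = 1e-10)

  expect_error(
    effector_effect(reg_through(10.9, tc = 25),
                    reg_through(5.4, label = "stripped"), 7.2),
    "temperature"
  )
})

test_that("summarize_effects populates available conditions only", {
  regs <- list(
    "stripped" = reg_through(5.4, label = "stripped"),
    "KCl" = reg_through(7.5, label = "KCl"),
    "DPG" = reg_through(8.0, label = "DPG"),
    "KCl+DPG" = reg_through(10.9, label = "KCl+DPG")
  )
  eff <- summarize_effects(regs, 7.2)
  expect_equal(eff$cl_effect$delta_log_p50, log10(7.5 / 5.4),
               tolerance = 1e-12)
  expect_equal(eff$dpg_effect$delta_log_p50, log10(8.0 / 5.4),
               tolerance = 1e-12)
  expect_equal(eff$combined_effect$delta_log_p50, log10(10.9 / 5.4),
               tolerance = 1e-12)

  part <- summarize_effects(regs[c("stripped", "KCl")], 7.2)
  expect_null(part$dpg_effect)
  expect_null(part$combined_effect)
  expect_false(is.null(part$cl_effect))

  expect_error(summarize_effects(regs[c("KCl", "DPG")], 7.2), "stripped")
})

test_that("equal T/R DPG binding constants abolish the DPG effect", {
  # analogue of deleting the beta82 DPG binding site: state-independent
  # binding contributes nothing to L, so the effect is exactly zero
  params <- mwc_params(dpg_kT = 5e-4, dpg_kR = 5e-4)
  phs <- c(6.9, 7.2, 7.5, 7.8)
  regs <- list(
    "stripped" = fit_logp50_vs_ph(fits_from_model(params, phs)),
    "DPG" = fit_logp50_vs_ph(
      fits_from_model(params, phs, label = "DPG", dpg_f = 2)
    )
  )
  eff <- summarize_effects(regs, 7.2)
  expect_equal(eff$dpg_effect$delta_log_p50, 0, tolerance = 1e-9)
})

test_that("near-zero DPG responders keep a measurable chloride effect", {
  # hemoglobin with DPG binding disabled but chloride binding intact
  params <- mwc_params(dpg_kT = 5e-4, dpg_kR = 5e-4)
  phs <- c(6.9, 7.2, 7.5, 7.8)
  regs <- list(
    "stripped" = fit_logp50_vs_ph(fits_from_model(params, phs)),
    "KCl" = fit_logp50_vs_ph(
      fits_from_model(params, phs, label = "KCl", kcl = 0.1)
    )
  )
  eff <- summarize_effects(regs, 7.2)
  expect_gt(eff$cl_effect$delta_log_p50, 0.05)
})

test_that("effects are log-additive in the strongly T-dominated limit", {
  # with non-interacting T-state sites and the T state dominant at P50 for
  # all conditions, logP50 ~ const + logL/4, so combined ~ dpg + cl
  params <- mwc_params(L0 = 1e7, kR = 0.1, kT = 100,
                       dpg_kT = 1e-4, dpg_kR = 1e4,
                       cl_kT = 0.05, cl_kR = 1e4, m_cl = 2)
  phs <- c(6.9, 7.2, 7.5, 7.8)
  regs <- list(
    "stripped" = fit_logp50_vs_ph(fits_from_model(params, phs)),
    "DPG" = fit_logp50_vs_ph(
      fits_from_model(params, phs, label = "DPG", dpg_f = 2)
    ),
    "KCl" = fit_logp50_vs_ph(
      fits_from_model(params, phs, label = "KCl", kcl = 0.1)
    ),
    "KCl+DPG" = fit_logp50_vs_ph(
      fits_from_model(params, phs, label = "KCl+DPG", kcl = 0.1, dpg_f = 2)
    )
  )
  eff <- summarize_effects(regs, 7.2)
  expect_lt(abs(eff$combined_effect$delta_log_p50 -
                  (eff$dpg_effect$delta_log_p50 +
                     eff$cl_effect$delta_log_p50)), 0.02)
})
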