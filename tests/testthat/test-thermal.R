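test_that("van't Hoff isochore reproduces hand-computed values", {
  # equal P50 at both temperatures: no temperature dependence
  expect_equal(vant_hoff_dh(8, 8, 298.15, 310.15), 0, tolerance = 1e-12)

  # P50 doubling from 25 to 37 C: dH = 2.303 R log10(1/2) / (1/T1 - 1/T2)
  dh <- vant_hoff_dh(5, 10, 298.15, 310.15)
  dh_hand <- 2.303 * 8.314 * (log10(5) - log10(10)) /
    (1 / 298.15 - 1 / 310.15) / 1000
  expect_equal(dh, dh_hand, tolerance = 1e-12)
  expect_equal(dh, -44.416, tolerance = 1e-3)

  # solubilization correction: +12.55 toward less exothermic
  expect_equal(correct_solubilization(dh), dh + 12.55, tolerance = 1e-12)
  expect_equal(correct_solubilization(-44.416), -31.866, tolerance = 1e-3)
  expect_equal(correct_solubilization(0), 12.55)
  expect_equal(correct_solubilization(0, correction_kj = -12.55), -12.55)

  expect_error(vant_hoff_dh(5, 10, 310.15, 310.15), "differ")
  expect_error(vant_hoff_dh(5, 10, 310.15, 298.15), "lower")
  expect_error(vant_hoff_dh(-5, 10, 298.15, 310.15), "positive")
})

test_that("sign law: P50 rising with temperature implies exothermic dH", {
  set.seed(13)
  for (i in 1:25) {
    p_low <- 10^runif(1, -0.5, 1.5)
    ratio <- 10^runif(1, 0.01, 0.6)
    t1 <- runif(1, 273, 305)
    t2 <- t1 + runif(1, 5, 20)
    expect_lt(vant_hoff_dh(p_low, p_low * ratio, t1, t2), 0)
    expect_gt(vant_hoff_dh(p_low * ratio, p_low, t1, t2), 0)
  }
})

test_that("dH is additive over log-ratio decompositions", {
  set.seed(14)
  for (i in 1:10) {
    p <- 10^runif(3, -0.5, 1.5)
    t1 <- 298.15; t2 <- 310.15
    expect_equal(
      vant_hoff_dh(p[1], p[2], t1, t2) + vant_hoff_dh(p[2], p[3], t1, t2),
      vant_hoff_dh(p[1], p[3], t1, t2),
      tolerance = 1e-10
    )
  }
})

test_that("pipeline dH equals the heme oxygenation enthalpy when all other enthalpies vanish", {
  params <- mwc_params(dh_l = 0, dh_dpg = 0, dh_cl = 0, dh_h = 0,
                       dh_o2 = -59)
  phs <- c(6.9, 7.2, 7.5, 7.8)
  regs <- list(
    fit_logp50_vs_ph(fits_from_model(params, phs, tc = 25)),
    fit_logp50_vs_ph(fits_from_model(params, phs, tc = 37))
  )
  th <- thermal_summary(regs, 7.2)
  expect_lt(abs(th$dh_raw - (-59)), 0.25)
  expect_lt(abs(th$dh_corrected - (-59 + 12.55)), 0.25)

  # ground-truth check without the fitting layer; the isochore uses the
  # conventional printed constant 2.303 rather than ln(10), a 0.018% offset
  tr <- true_dh(params, make_cond())
  expect_lt(abs(tr$dh_raw - (-59)), 0.02)
})

test_that("thermal_summary propagates SEs and enforces its contracts", {
  params <- mwc_params()
  phs <- c(6.9, 7.2, 7.5, 7.8)
  mk <- function(tc, seed) {
    set.seed(seed)
    fit_logp50_vs_ph(lapply(phs, function(ph) {
      fit_hill(simulate_oec(params, make_cond(ph = ph, tc = tc),
                            noise_sd = 0.005))
    }))
  }
  regs <- list(mk(25, 1), mk(37, 2))
  th <- thermal_summary(regs, 7.2)
  expect_gt(th$se_dh, 0)
  cc <- 2.303 * 8.314 / (1 / th$t1 - 1 / th$t2) / 1000
  expect_equal(th$se_dh,
               abs(cc) * sqrt(se_pred(regs[[1]], 7.2)^2 +
                                se_pred(regs[[2]], 7.2)^2),
               tolerance = 1e-10)
  expect_equal(th$dh_corrected, th$dh_raw + 12.55, tolerance = 1e-12)

  expect_error(thermal_summary(regs[1], 7.2), "exactly two")
  expect_error(thermal_summary(c(regs, regs[1]), 7.2), "exactly two")
})

test_that("exothermic T-state effector binding makes dH' strictly less negative", {
  # monotone below the allosteric saturation point of the effector; at high
  # concentrations the T state is pinned at P50 and the oxygenation-linked
  # release (hence the enthalpy offset) rolls back toward the stripped value
  params <- mwc_params(dh_l = 0, dh_h = 0, dh_cl = -30)
  dh_at <- function(cl) {
    cond <- condition(ph = 7.2, temp_c = 37, kcl = cl, dpg = 0,
                      heme_conc = 0.25e-3)
    true_dh(params, cond)$dh_corrected
  }
  dh_low <- vapply(c(0, 0.005, 0.01, 0.02, 0.03), dh_at, numeric(1))
  expect_true(all(diff(dh_low) > 0))
  expect_true(all(dh_low < 0))
  # every effector concentration leaves dH' less negative than stripped
  dh_wide <- vapply(c(0.05, 0.1, 0.2, 0.5), dh_at, numeric(1))
  expect_true(all(dh_wide > dh_low[1]))
})
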