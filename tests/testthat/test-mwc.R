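test_that("saturation matches the ligation-state partition-function oracle", {
  set.seed(77)
  cond0 <- make_cond(ph = 7.35, kcl = 0.08, dpg_f = 1.5)
  for (i in 1:1000) {
    params <- mwc_params(
      L0 = 10^runif(1, 1, 7),
      kR = 10^runif(1, -1.5, 0.5),
      kT = 10^runif(1, 0.6, 2.5),
      dpg_kT = 10^runif(1, -6, -3), dpg_kR = 10^runif(1, -3, -1),
      cl_kT = 10^runif(1, -2.5, -0.5), cl_kR = 10^runif(1, -1, 1),
      pka_T = runif(1, 7.0, 7.8), pka_R = runif(1, 6.3, 7.0),
      m_dpg = sample(0:2, 1), m_cl = sample(0:4, 1), m_h = sample(0:3, 1)
    )
    po2 <- 10^runif(1, -2, 3)
    # evaluate at t_ref so the oracle shares the unscaled constants
    L <- allosteric_L(params, cond0)
    expect_equal(mwc_saturation(params, po2, cond0),
                 saturation_oracle(L, params$kR, params$kT, po2),
                 tolerance = 1e-10)
  }
})

test_that("allosteric_L reduces correctly in its limits", {
  p <- mwc_params(m_h = 0)
  # no effectors at the reference temperature: L = L0
  expect_equal(allosteric_L(p, make_cond()), p$L0, tolerance = 1e-12)

  # state-independent DPG binding contributes a unit factor at any [DPG]
  p_eq <- mwc_params(dpg_kT = 3e-4, dpg_kR = 3e-4, m_h = 0)
  expect_equal(allosteric_L(p_eq, make_cond(dpg_f = 2)),
               allosteric_L(p_eq, make_cond()), tolerance = 1e-12)

  # saturating T-state-only effector: factor -> [e]/K_T per site
  p_sat <- mwc_params(cl_kT = 1e-6, cl_kR = 1e12, m_cl = 1, m_h = 0)
  cond <- make_cond(kcl = 0.1)
  expect_equal(allosteric_L(p_sat, cond) / p_sat$L0,
               0.1 / 1e-6, tolerance = 1e-4)
})

test_that("saturation curve has the required shape", {
  p <- mwc_params()
  cond <- make_cond()
  po2 <- 10^seq(-3, 3, length.out = 200)
  y <- mwc_saturation(p, po2, cond)
  expect_equal(mwc_saturation(p, 0, cond), 0)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0 & y < 1))
  expect_gt(mwc_saturation(p, 1e6, cond), 0.9999)

  # pure R-state limit: hyperbola with P50 = kR
  p_r <- mwc_params(L0 = 1e-9, m_h = 0)
  expect_equal(true_p50(p_r, cond), p_r$kR, tolerance = 1e-6)
  a <- 2.7
  expect_equal(mwc_saturation(p_r, a * p_r$kR, cond), a / (1 + a),
               tolerance = 1e-8)

  # identical states (c -> 1): non-cooperative hyperbola for any L
  p_c1 <- mwc_params(kR = 1, kT = 1 + 1e-9, L0 = 1e4, m_h = 0)
  expect_equal(true_n50(p_c1, cond), 1, tolerance = 1e-5)
  expect_equal(mwc_saturation(p_c1, 3, cond), 3 / (1 + 3), tolerance = 1e-6)
})

test_that("true_p50 agrees with a dense grid argmin and is monotone in L0", {
  p <- mwc_params()
  cond <- make_cond(kcl = 0.1, dpg_f = 2)
  lp <- seq(-2, 3, length.out = 200001)
  y <- mwc_saturation(p, 10^lp, cond)
  grid_p50 <- 10^lp[which.min(abs(y - 0.5))]
  expect_equal(true_p50(p, cond), grid_p50, tolerance = 1e-4)

  p50s <- vapply(c(1e3, 1e4, 1e5, 1e6, 1e7), function(L0) {
    true_p50(mwc_params(L0 = L0), cond)
  }, numeric(1))
  expect_true(all(diff(p50s) > 0))
})

test_that("true_n50 lies in the tetramer bounds and matches a noiseless Hill fit", {
  set.seed(99)
  for (i in 1:20) {
    p <- mwc_params(L0 = 10^runif(1, 2, 6), kR = 10^runif(1, -1, 0),
                    kT = 10^runif(1, 1, 2))
    cond <- make_cond(ph = runif(1, 6.9, 7.8))
    n <- true_n50(p, cond)
    expect_gte(n, 1 - 1e-6)
    expect_lte(n, 4 + 1e-6)
  }
  # strongly two-state regime: the Hill plot is essentially linear in the
  # 30-70% band and the chord slope matches the analytic slope
  p <- mwc_params(L0 = 1e5, kR = 0.35, kT = 3500)
  f <- fit_hill(simulate_oec(p, make_cond(), noise_sd = 0))
  expect_equal(f$n50, true_n50(p, make_cond()), tolerance = 1e-3)
})

test_that("effector monotonicity: T-preferential binding never lowers P50", {
  p <- mwc_params()
  p50_dpg <- vapply(c(0, 0.5, 1, 2, 4), function(f) {
    true_p50(p, make_cond(dpg_f = f))
  }, numeric(1))
  expect_true(all(diff(p50_dpg) > 0))
  p50_cl <- vapply(c(0, 0.05, 0.1, 0.2), function(kcl) {
    true_p50(p, make_cond(kcl = kcl))
  }, numeric(1))
  expect_true(all(diff(p50_cl) > 0))
})

test_that("simulate_oec is protocol-faithful and seed-deterministic", {
  p <- mwc_params()
  cond <- make_cond()
  s1 <- simulate_oec(p, cond, k_tensions = 4, noise_sd = 0.005, seed = 42)
  s2 <- simulate_oec(p, cond, k_tensions = 4, noise_sd = 0.005, seed = 42)
  expect_identical(s1$po2, s2$po2)
  expect_identical(s1$saturation, s2$saturation)
  s3 <- simulate_oec(p, cond, k_tensions = 4, noise_sd = 0.005, seed = 43)
  expect_false(identical(s1$saturation, s3$saturation))

  # true saturations at the chosen tensions sit strictly inside (0.30, 0.70)
  y_true <- mwc_saturation(p, s1$po2, cond)
  expect_true(all(y_true > 0.30 & y_true < 0.70))
  expect_true(all(diff(s1$po2) > 0))
  for (k in 3:5) {
    expect_length(simulate_oec(p, cond, k_tensions = k, seed = 1)$po2, k)
  }

  # noiseless chord fit: near-exact in the high-cooperativity regime,
  # curvature-bounded at the realistic defaults
  p_lin <- mwc_params(L0 = 1e5, kR = 0.35, kT = 350)
  f_lin <- fit_hill(simulate_oec(p_lin, cond, noise_sd = 0))
  expect_equal(f_lin$p50, true_p50(p_lin, cond), tolerance = 1e-3)
  f_def <- fit_hill(simulate_oec(p, cond, noise_sd = 0))
  expect_equal(f_def$p50, true_p50(p, cond), tolerance = 1e-2)
  expect_equal(f_def$n50, true_n50(p, cond), tolerance = 2e-2)
})

test_that("simulated saturation noise respects the open-unit-interval redraw", {
  p <- mwc_params()
  cond <- make_cond()
  set.seed(8)
  for (i in 1:50) {
    s <- simulate_oec(p, cond, noise_sd = 0.15, seed = NULL)
    expect_true(all(s$saturation > 0.01 & s$saturation < 0.99))
  }
})

test_that("simulate_solubility is exact when noiseless and reproducible", {
  mol <- seq(0, 3.5, by = 0.5)
  s <- simulate_solubility(2.8, 0.15, mol, noise_sd = 0, sample_id = "x")
  expect_equal(s$soluble_signal, 1 / (1 + exp((mol - 2.8) / 0.15)),
               tolerance = 1e-12)
  a <- simulate_solubility(2.8, 0.15, mol, noise_sd = 0.01, seed = 3)
  b <- simulate_solubility(2.8, 0.15, mol, noise_sd = 0.01, seed = 3)
  expect_identical(a$soluble_signal, b$soluble_signal)
})

test_that("simulated panels carry the declared conditions", {
  p <- mwc_params()
  panel <- simulate_experiment(p, "hb1", ph_values = c(6.9, 7.5),
                               temps_c = c(25, 37),
                               condition_labels = c("stripped", "KCl+DPG"),
                               seed = 21)
  expect_length(panel, 2 * 2 * 2)
  labs <- vapply(panel, function(s) s$condition$label, character(1))
  expect_setequal(unique(labs), c("stripped", "KCl+DPG"))
  kdpg <- panel[[which(labs == "KCl+DPG")[1]]]
  expect_equal(kdpg$condition$kcl, 0.1)
  expect_equal(kdpg$condition$dpg, 2 * 0.25e-3 / 4)
  p2 <- simulate_experiment(p, "hb1", ph_values = c(6.9, 7.5),
                            temps_c = c(25, 37),
                            condition_labels = c("stripped", "KCl+DPG"),
                            seed = 21)
  expect_identical(vapply(panel, function(s) s$saturation[1], numeric(1)),
                   vapply(p2, function(s) s$saturation[1], numeric(1)))
})
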