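# Shared fixtures and independent oracles used across test files.

make_cond <- function(ph = 7.2, tc = 37, kcl = 0, dpg_f = 0,
                      heme = 0.25e-3, label = NULL) {
  condition(ph = ph, temp_c = tc, kcl = kcl, dpg_fold_excess = dpg_f,
            heme_conc = heme, label = label)
}

# Exact two-parameter Hill-function series: S = p^n / (p^n + p50^n)
make_hill_series <- function(p50, n50, po2, noise_sd = 0, seed = NULL,
                             cond = make_cond(), id = "hill") {
  if (!is.null(seed)) set.seed(seed)
  s <- po2^n50 / (po2^n50 + p50^n50)
  if (noise_sd > 0) s <- s + rnorm(length(s), 0, noise_sd)
  oec_series(id, cond, po2, s)
}

# Brute-force oracle for the Hill fit: iteratively refined grid search
# minimizing the Hill-space SSE over (log_p50, n50). Independent of lm().
hill_grid_oracle <- function(series, levels = 7, n_grid = 81) {
  x <- log10(series$po2)
  y <- log10(series$saturation / (1 - series$saturation))
  sy2 <- sum(y^2); sxy <- sum(x * y); sy <- sum(y)
  sx2 <- sum(x^2); sx <- sum(x); np <- length(x)
  sse <- function(a, b) {
    # sum_i (y_i - b * (x_i - a))^2, vectorized over equal-length a, b
    sy2 - 2 * b * (sxy - a * sy) + b^2 * (sx2 - 2 * a * sx + np * a^2)
  }
  lp_rng <- c(min(x) - 2, max(x) + 2)
  n_rng <- c(0.05, 8)
  for (lev in seq_len(levels)) {
    lp <- seq(lp_rng[1], lp_rng[2], length.out = n_grid)
    nn <- seq(n_rng[1], n_rng[2], length.out = n_grid)
    g <- expand.grid(a = lp, b = nn)
    i <- which.min(sse(g$a, g$b))
    a0 <- g$a[i]; b0 <- g$b[i]
    da <- diff(lp_rng) / (n_grid - 1)
    db <- diff(n_rng) / (n_grid - 1)
    lp_rng <- c(a0 - 2 * da, a0 + 2 * da)
    n_rng <- c(max(b0 - 2 * db, 1e-3), b0 + 2 * db)
  }
  list(log_p50 = a0, p50 = 10^a0, n50 = b0)
}

# Partition-function oracle for the two-state saturation: explicit 5-term
# ligation-state sums with binomial weights for each conformation.
saturation_oracle <- function(L, kR, kT, po2) {
  i <- 0:4
  w_r <- choose(4, i) * (po2 / kR)^i
  w_t <- L * choose(4, i) * (po2 / kT)^i
  sum((i / 4) * (w_r + w_t)) / sum(w_r + w_t)
}

# Minimal stand-in for a hill_fit when only (ph, log_p50) matter
fake_fit <- function(ph, log_p50, tc = 37, label = "stripped",
                     se_log_p50 = 0.002) {
  structure(
    list(condition = make_cond(ph = ph, tc = tc, label = label),
         log_p50 = log_p50, p50 = 10^log_p50, se_log_p50 = se_log_p50,
         n50 = 2.5, se_n50 = 0.05, r2 = 1, n_points = 4L, dof = 2L,
         sample_id = "fake", prenatal = FALSE),
    class = "hill_fit"
  )
}

# Noiseless pH panel -> list of hill fits, for regression-level tests
fits_from_model <- function(params, ph_values, tc = 37, label = "stripped",
                            kcl = 0, dpg_f = 0, k_tensions = 4) {
  lapply(ph_values, function(ph) {
    cond <- make_cond(ph = ph, tc = tc, kcl = kcl, dpg_f = dpg_f,
                      label = label)
    fit_hill(simulate_oec(params, cond, k_tensions = k_tensions,
                          noise_sd = 0, sample_id = "nf"))
  })
}

write_temp_csv <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Standard 12-row OEC table: 3 samples x 4 tensions, one condition each
example_oec_df <- function() {
  data.frame(
    sample = rep(c("hbA", "hbB", "hbC"), each = 4),
    ph = 7.2, temp_c = 37, kcl_M = 0, heme_mM = 0.25, dpg_fold = 0,
    po2_mmHg = rep(c(6, 8, 10, 14), 3),
    saturation = rep(c(0.32, 0.45, 0.55, 0.68), 3)
  )
}
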