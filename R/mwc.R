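#' Two-state allosteric model parameters
#'
#' Ground-truth parameters of the Monod-Wyman-Changeux (MWC) two-state model
#' used by the synthetic-data generator. A tetramer switches concertedly
#' between a low-affinity T state and a high-affinity R state; `L0` is the
#' T/R equilibrium constant of the deoxy protein under reference conditions
#' (stripped, proton-free, `t_ref`). O2 binds each of the four hemes with
#' per-site dissociation constants `kT > kR` (mm Hg), so `c = kR/kT` lies in
#' (0, 1). Heterotropic effectors act purely through `L`: DPG (one site per
#' tetramer, between the beta chains), chloride (`m_cl` independent sites) and
#' Bohr protons (`m_h` groups with T- and R-state pKa values) bind
#' state-dependently and so stabilize the deoxy conformation when their
#' T-state constants are tighter.
#'
#' Every equilibrium carries its own enthalpy (kJ mol-1): `dh_o2` for heme
#' oxygenation (default -59), `dh_l` for the T->R transition, `dh_dpg`,
#' `dh_cl`, `dh_h` for effector binding, and `dh_sol` for O2 solution in water
#' (magnitude 12.55; a property of the gas-tension measurement, not of the
#' protein). Binding constants follow the van't Hoff relation
#' `K(T) = K(t_ref) * exp[(dh/R) * (1/T - 1/t_ref)]` and `L0` scales
#' analogously with `dh_l`.
#'
#' @param L0 deoxy T/R equilibrium constant at reference conditions.
#' @param kR,kT per-site O2 dissociation constants, mm Hg (`kT > kR`).
#' @param dpg_kT,dpg_kR DPG dissociation constants, mol/L.
#' @param cl_kT,cl_kR chloride dissociation constants, mol/L.
#' @param pka_T,pka_R Bohr-group pKa in T and R state.
#' @param m_dpg,m_cl,m_h site counts per tetramer (non-negative integers).
#' @param dh_o2,dh_l,dh_dpg,dh_cl,dh_h,dh_sol enthalpies, kJ mol-1.
#' @param t_ref reference temperature, kelvin (default 310.15 = 37 C).
#' @param gas_constant R, J mol-1 K-1.
#' @return object of class `mwc_params`.
#' @export
mwc_params <- function(L0 = 1e5, kR = 0.35, kT = 35,
                       dpg_kT = 6e-5, dpg_kR = 2e-2,
                       cl_kT = 0.125, cl_kR = 0.5,
                       pka_T = 7.45, pka_R = 6.75,
                       m_dpg = 1L, m_cl = 4L, m_h = 2L,
                       dh_o2 = -59, dh_l = 20, dh_dpg = -30, dh_cl = -20,
                       dh_h = -30, dh_sol = 12.55,
                       t_ref = 310.15, gas_constant = 8.314) {
  x <- structure(
    list(L0 = L0, kR = kR, kT = kT,
         dpg_kT = dpg_kT, dpg_kR = dpg_kR,
         cl_kT = cl_kT, cl_kR = cl_kR,
         pka_T = pka_T, pka_R = pka_R,
         m_dpg = as.integer(m_dpg), m_cl = as.integer(m_cl),
         m_h = as.integer(m_h),
         dh_o2 = dh_o2, dh_l = dh_l, dh_dpg = dh_dpg, dh_cl = dh_cl,
         dh_h = dh_h, dh_sol = dh_sol,
         t_ref = t_ref, gas_constant = gas_constant),
    class = "mwc_params"
  )
  validate_mwc_params(x)
}

validate_mwc_params <- function(p) {
  stopifnot(inherits(p, "mwc_params"))
  pos <- c("L0", "kR", "kT", "dpg_kT", "dpg_kR", "cl_kT", "cl_kR",
           "t_ref", "gas_constant")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 ||
        !is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("mwc_params: ", nm, " must be a single positive number")
    }
  }
  if (p$kT <= p$kR) stop("mwc_params: kT must exceed kR (c = kR/kT in (0,1))")
  for (nm in c("m_dpg", "m_cl", "m_h")) {
    if (p[[nm]] < 0) stop("mwc_params: ", nm, " must be >= 0")
  }
  p
}

#' @export
print.mwc_params <- function(x, ...) {
  cat(sprintf(
    "<mwc_params> L0 = %.4g, kR = %.4g, kT = %.4g mm Hg (c = %.4g)\n",
    x$L0, x$kR, x$kT, x$kR / x$kT
  ))
  cat(sprintf("  DPG K_T/K_R = %.3g/%.3g M (x%d), Cl K_T/K_R = %.3g/%.3g M (x%d), pKa T/R = %.2f/%.2f (x%d)\n",
              x$dpg_kT, x$dpg_kR, x$m_dpg, x$cl_kT, x$cl_kR, x$m_cl,
              x$pka_T, x$pka_R, x$m_h))
  cat(sprintf("  dH (kJ/mol): O2 %.1f, T->R %.1f, DPG %.1f, Cl %.1f, H+ %.1f, sol %.2f; t_ref %.2f K\n",
              x$dh_o2, x$dh_l, x$dh_dpg, x$dh_cl, x$dh_h, x$dh_sol, x$t_ref))
  invisible(x)
}

# van't Hoff temperature scaling of a dissociation (or T/R equilibrium)
# constant: d ln K / d(1/T) = dh/R with dh the binding (or T->R) enthalpy.
scale_k <- function(k_ref, dh_kj, temp_k, t_ref, gas_constant) {
  k_ref * exp((dh_kj * 1000 / gas_constant) * (1 / temp_k - 1 / t_ref))
}

#' Effective allosteric constant under a condition
#'
#' The deoxy T/R equilibrium constant under a given chemical/thermal context:
#' `L_eff = L0(T) * prod_e [(1 + [e]/K_Te) / (1 + [e]/K_Re)]^m_e`
#' over DPG, chloride and protons, with `[H+] = 10^-pH` and proton
#' "dissociation constants" `10^-pKa`. All constants are first scaled to the
#' condition temperature by the van't Hoff relation (see [mwc_params()]).
#'
#' @param params an [mwc_params()].
#' @param cond an [condition()].
#' @return effective L (positive scalar).
#' @export
allosteric_L <- function(params, cond) {
  validate_mwc_params(params)
  validate_condition(cond)
  tk <- cond$temperature
  R <- params$gas_constant
  tr <- params$t_ref
  L <- scale_k(params$L0, params$dh_l, tk, tr, R)

  factor_e <- function(conc, kT_ref, kR_ref, dh, m) {
    if (m == 0 || conc == 0) return(1)
    kT <- scale_k(kT_ref, dh, tk, tr, R)
    kR <- scale_k(kR_ref, dh, tk, tr, R)
    ((1 + conc / kT) / (1 + conc / kR))^m
  }
  h <- 10^(-cond$ph)
  L *
    factor_e(cond$dpg, params$dpg_kT, params$dpg_kR, params$dh_dpg,
             params$m_dpg) *
    factor_e(cond$kcl, params$cl_kT, params$cl_kR, params$dh_cl,
             params$m_cl) *
    factor_e(h, 10^(-params$pka_T), 10^(-params$pka_R), params$dh_h,
             params$m_h)
}

#' Fractional saturation of the two-state model
#'
#' With `alpha = PO2/kR(T)` and `c = kR(T)/kT(T)`:
#' `Y = [alpha (1+alpha)^3 + L c alpha (1 + c alpha)^3] /
#'      [(1+alpha)^4 + L (1 + c alpha)^4]`,
#' the tetramer MWC saturation function. Y is strictly increasing in PO2,
#' Y(0) = 0 and Y -> 1 as PO2 -> Inf.
#'
#' @param params an [mwc_params()].
#' @param po2 oxygen tension(s), mm Hg, >= 0 (vectorized).
#' @param cond an [condition()].
#' @return saturation fraction(s) in [0, 1).
#' @export
mwc_saturation <- function(params, po2, cond) {
  stopifnot(all(is.finite(po2)), all(po2 >= 0))
  tk <- cond$temperature
  kR <- scale_k(params$kR, params$dh_o2, tk, params$t_ref,
                params$gas_constant)
  kT <- scale_k(params$kT, params$dh_o2, tk, params$t_ref,
                params$gas_constant)
  L <- allosteric_L(params, cond)
  a <- po2 / kR
  cc <- kR / kT
  num <- a * (1 + a)^3 + L * cc * a * (1 + cc * a)^3
  den <- (1 + a)^4 + L * (1 + cc * a)^4
  num / den
}

#' True P50 of the forward model
#'
#' The unique root of `Y(PO2) = 1/2`, found by bisection on
#' log10 PO2 in [-6, 4] (i.e. PO2 in [1e-6, 1e4] mm Hg) to relative
#' tolerance 1e-9.
#'
#' @inheritParams mwc_saturation
#' @return P50 in mm Hg.
#' @export
true_p50 <- function(params, cond) {
  f <- function(lp) mwc_saturation(params, 10^lp, cond) - 0.5
  if (f(-6) > 0 || f(4) < 0) {
    stop("P50 outside [1e-6, 1e4] mm Hg: implausible parameters")
  }
  r <- stats::uniroot(f, c(-6, 4), tol = 1e-12)
  10^r$root
}

#' True Hill coefficient at half saturation
#'
#' Analytic Hill slope `d log10[Y/(1-Y)] / d log10 PO2` evaluated at the true
#' P50 by a centered finite difference with step `1e-4` in log10 PO2. For a
#' tetramer the value lies in [1, 4].
#'
#' @inheritParams mwc_saturation
#' @return dimensionless cooperativity coefficient.
#' @export
true_n50 <- function(params, cond) {
  lp <- log10(true_p50(params, cond))
  d <- 1e-4
  yl <- mwc_saturation(params, 10^(lp - d), cond)
  yh <- mwc_saturation(params, 10^(lp + d), cond)
  (log10(yh / (1 - yh)) - log10(yl / (1 - yl))) / (2 * d)
}

#' True Bohr slope of the forward model
#'
#' Centered finite difference of `log10 true_p50` with respect to pH,
#' evaluated at `ph` (default 7.35, the midpoint of the Bohr window) with the
#' other condition fields held fixed.
#'
#' @param params an [mwc_params()].
#' @param cond an [condition()]; its `ph` field is overridden.
#' @param ph pH at which the derivative is taken.
#' @param dph half step, pH units.
#' @return dlogP50/dpH.
#' @export
true_bohr <- function(params, cond, ph = 7.35, dph = 1e-3) {
  at <- function(p) {
    c2 <- cond
    c2$ph <- p
    log10(true_p50(params, c2))
  }
  (at(ph + dph) - at(ph - dph)) / (2 * dph)
}

#' True corrected oxygenation enthalpy of the forward model
#'
#' Evaluates the true P50 at two temperatures (condition otherwise fixed),
#' applies the van't Hoff isochore and the solubilization correction
#' (`params$dh_sol`). This is the ground truth the pipeline's
#' [thermal_summary()] estimates from simulated data.
#'
#' @param params an [mwc_params()].
#' @param cond an [condition()]; its temperature field is overridden.
#' @param temps_c the two temperatures, degrees Celsius.
#' @return list with `dh_raw` and `dh_corrected`, kJ mol-1 O2.
#' @export
true_dh <- function(params, cond, temps_c = c(25, 37)) {
  stopifnot(length(temps_c) == 2)
  temps_c <- sort(temps_c)
  at <- function(tc) {
    c2 <- cond
    c2$temperature <- celsius_to_kelvin(tc)
    true_p50(params, c2)
  }
  dh_raw <- vant_hoff_dh(at(temps_c[1]), at(temps_c[2]),
                         celsius_to_kelvin(temps_c[1]),
                         celsius_to_kelvin(temps_c[2]),
                         gas_constant = params$gas_constant)
  list(dh_raw = dh_raw,
       dh_corrected = correct_solubilization(dh_raw, params$dh_sol))
}

#' Simulate one oxygen-equilibrium series
#'
#' Emulates the thin-film protocol: `k_tensions` target saturations equally
#' spaced strictly inside the 30--70% band, tensions obtained by inverting the true
#' saturation curve, and observed saturations equal to the true value plus
#' Gaussian noise (sd `noise_sd`), redrawn while outside (0.01, 0.99) so the
#' logit stays finite. Deterministic for a fixed seed.
#'
#' @param params an [mwc_params()].
#' @param cond an [condition()].
#' @param k_tensions number of oxygen tensions, 3--5.
#' @param noise_sd saturation noise SD (default 0.005).
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @param sample_id sample identifier for the series.
#' @param prenatal prenatal flag carried into the series.
#' @return an [oec_series()].
#' @export
simulate_oec <- function(params, cond, k_tensions = 4, noise_sd = 0.005,
                         seed = NULL, sample_id = "sim", prenatal = FALSE) {
  stopifnot(k_tensions %in% 3:5, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  targets <- 0.30 + 0.40 * seq_len(k_tensions) / (k_tensions + 1)
  po2 <- vapply(targets, function(s) {
    f <- function(lp) mwc_saturation(params, 10^lp, cond) - s
    10^stats::uniroot(f, c(-6, 4), tol = 1e-12)$root
  }, numeric(1))
  y_true <- mwc_saturation(params, po2, cond)
  obs <- vapply(y_true, function(y) {
    repeat {
      v <- y + stats::rnorm(1, 0, noise_sd)
      if (noise_sd == 0 || (v > 0.01 && v < 0.99)) return(v)
    }
  }, numeric(1))
  oec_series(sample_id, cond, po2, obs, prenatal = prenatal)
}

#' Simulate a full measurement panel for one hemoglobin
#'
#' Generates one [simulate_oec()] series per combination of pH, temperature
#' and effector condition, emulating a complete tonometry experiment for one
#' sample. One seed governs the whole panel (series are drawn sequentially
#' from a single seeded stream, so the panel is reproducible as a unit).
#'
#' @param params an [mwc_params()].
#' @param sample_id sample identifier.
#' @param ph_values vector of pH values.
#' @param temps_c vector of temperatures, degrees Celsius.
#' @param condition_labels subset of `c("stripped", "KCl", "DPG", "KCl+DPG")`.
#' @param heme_conc heme concentration, mol/L (default 0.25 mM).
#' @param kcl KCl molarity used for chloride conditions (default 0.1 M).
#' @param dpg_fold_excess DPG fold excess over tetramer for DPG conditions
#'   (default 2).
#' @param k_tensions,noise_sd,prenatal passed to [simulate_oec()].
#' @param seed integer seed for the panel.
#' @return list of [oec_series()].
#' @export
simulate_experiment <- function(params, sample_id,
                                ph_values = c(6.9, 7.2, 7.5, 7.8),
                                temps_c = c(25, 37),
                                condition_labels = c("stripped", "KCl",
                                                     "DPG", "KCl+DPG"),
                                heme_conc = 0.25e-3, kcl = 0.1,
                                dpg_fold_excess = 2,
                                k_tensions = 4, noise_sd = 0.005,
                                prenatal = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (lab in condition_labels) {
    kcl_i <- if (grepl("KCl", lab, fixed = TRUE)) kcl else 0
    dpg_f <- if (grepl("DPG", lab, fixed = TRUE)) dpg_fold_excess else 0
    for (tc in temps_c) {
      for (ph in ph_values) {
        cond <- condition(ph = ph, temp_c = tc, kcl = kcl_i,
                          dpg_fold_excess = dpg_f, heme_conc = heme_conc,
                          label = lab)
        out[[length(out) + 1]] <- simulate_oec(
          params, cond, k_tensions = k_tensions, noise_sd = noise_sd,
          seed = NULL, sample_id = sample_id, prenatal = prenatal
        )
      }
    }
  }
  out
}

#' Simulate an ammonium-sulfate solubility series
#'
#' Logistic soluble fraction `1 / (1 + exp((M - midpoint)/slope))` plus
#' Gaussian noise, clamped to [0, 1.05]; the 0 M control is always included.
#'
#' @param midpoint salting-out midpoint, mol/L.
#' @param slope transition width, mol/L.
#' @param molarities measured molarities (0 M is added if absent).
#' @param noise_sd Gaussian noise SD on the fraction scale.
#' @param seed integer seed, or `NULL`.
#' @param sample_id sample identifier.
#' @return a [solubility_series()].
#' @export
simulate_solubility <- function(midpoint, slope,
                                molarities = seq(0, 3.5, by = 0.5),
                                noise_sd = 0.01, seed = NULL,
                                sample_id = "sim") {
  stopifnot(midpoint > 0, slope > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (!any(molarities == 0)) molarities <- c(0, molarities)
  frac <- 1 / (1 + exp((molarities - midpoint) / slope))
  obs <- pmin(pmax(frac + stats::rnorm(length(frac), 0, noise_sd), 0), 1.05)
  solubility_series(sample_id, molarities, obs)
}
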