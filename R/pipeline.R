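#' Run the full oxygen-equilibrium analysis pipeline
#'
#' For each hemoglobin sample: fits Hill plots to every series, regresses
#' log10 P50 on pH per (condition, temperature), standardizes P50 and n50 at
#' the reference pH (7.20, or 7.10 for prenatal-flagged samples), computes the
#' Bohr coefficient per condition, effector effects versus the stripped
#' condition, the van't Hoff oxygenation enthalpy between the two assay
#' temperatures (plus a stripped-Hb report at pH 7.8, where oxygenation-linked
#' proton binding is minimal), and, when solubility data are supplied, the
#' salting-out summary.
#'
#' A stage failure (too few pH points, a missing temperature, ...) voids only
#' the affected summary cell; the reason is collected in `warnings`. Output is
#' deterministic for fixed inputs and configuration.
#'
#' @param oec list of [oec_series()] or a path readable by [read_oec_table()].
#' @param solubility optional list of [solubility_series()] or a path readable
#'   by [read_solubility_table()].
#' @param config run configuration, see [default_config()].
#' @return list of `hb_summary` objects (one per sample), each with fields
#'   `hb_id`, `reference_ph`, `conditions` (per condition x temperature:
#'   standardized P50/n50 with SEs, Bohr), `effects`, `thermal`,
#'   `solubility`, `warnings` and `provenance`.
#' @export
run_pipeline <- function(oec, solubility = NULL, config = default_config()) {
  if (is.character(oec)) oec <- read_oec_table(oec, config)
  if (is.character(solubility)) solubility <- read_solubility_table(solubility)
  stopifnot(length(oec) > 0)
  samples <- unique(vapply(oec, function(s) s$sample_id, character(1)))
  sol_ids <- vapply(solubility %||% list(), function(s) s$sample_id,
                    character(1))
  lapply(samples, function(id) {
    series <- Filter(function(s) s$sample_id == id, oec)
    sol <- if (id %in% sol_ids) {
      solubility[[match(id, sol_ids)]]
    }
    summarize_hb(id, series, sol, config)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

summarize_hb <- function(id, series, sol, config) {
  warnings <- character(0)
  note <- function(stage, cond_key, msg) {
    warnings[[length(warnings) + 1]] <<-
      sprintf("[%s | %s] %s: %s", id, cond_key, stage, msg)
  }
  try_cell <- function(stage, cond_key, expr) {
    tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        note(stage, cond_key, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        note(stage, cond_key, conditionMessage(e))
        NULL
      }
    )
  }

  prenatal <- any(vapply(series, function(s) s$prenatal, logical(1)))
  ph_ref <- if (prenatal) config$reference_ph_prenatal else
    config$reference_ph_adult

  # Hill fit per series
  fits <- list()
  for (s in series) {
    key <- sprintf("%s@%.1fC pH %.2f", s$condition$label,
                   kelvin_to_celsius(s$condition$temperature), s$condition$ph)
    f <- try_cell("hill_fit", key, fit_hill(s))
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }

  # group fits by (condition label, temperature)
  grp_key <- vapply(fits, function(f) {
    sprintf("%s@%.6f", f$condition$label, f$condition$temperature)
  }, character(1))
  groups <- split(fits, grp_key)

  regs <- list()
  cond_rows <- list()
  for (g in groups) {
    lab <- g[[1]]$condition$label
    tk <- g[[1]]$condition$temperature
    key <- sprintf("%s@%.1fC", lab, kelvin_to_celsius(tk))
    reg <- if (length(g) >= 2) {
      try_cell("ph_regression", key,
               fit_logp50_vs_ph(g, weight_by_se = isTRUE(config$weight_by_se)))
    }
    std <- if (!is.null(reg)) try_cell("p50_at_ph", key, p50_at_ph(reg, ph_ref))
    bohr <- try_cell("bohr", key, bohr_coefficient(g, config$bohr_ph_range))
    n50_std <- try_cell("n50", key, standardize_n50(g, ph_ref))
    if (!is.null(reg)) regs[[paste(lab, format(tk))]] <- reg
    cond_rows[[key]] <- list(
      condition_label = lab, temperature = tk,
      ph_regression = reg,
      p50 = std$p50 %||% NA_real_, se_p50 = std$se_p50 %||% NA_real_,
      n50 = n50_std$n50 %||% NA_real_, se_n50 = n50_std$se %||% NA_real_,
      bohr = bohr$phi %||% NA_real_, se_bohr = bohr$se %||% NA_real_,
      n_fits = length(g)
    )
    if (is.null(std)) note("p50_at_ph", key, "standardized P50 absent")
  }

  # effector effects at each temperature with a stripped regression
  temps <- unique(vapply(regs, function(r) r$temperature, numeric(1)))
  effects <- list()
  for (tk in temps) {
    at_t <- Filter(function(r) abs(r$temperature - tk) < 1e-9, regs)
    names(at_t) <- vapply(at_t, function(r) r$condition_label, character(1))
    key <- sprintf("effects@%.1fC", kelvin_to_celsius(tk))
    e <- try_cell("effects", key, summarize_effects(at_t, ph_ref))
    if (!is.null(e)) effects[[sprintf("%.6f", tk)]] <- e
  }

  # thermal analysis per condition with exactly two temperatures
  thermal <- list()
  by_lab <- split(regs, vapply(regs, function(r) r$condition_label,
                               character(1)))
  for (lab in names(by_lab)) {
    rr <- by_lab[[lab]]
    if (length(rr) == 2) {
      th <- try_cell("thermal", lab, thermal_summary(rr, ph_ref, config))
      if (!is.null(th)) thermal[[lab]] <- th
      if (lab == "stripped" &&
          !is.null(config$stripped_dh_ph) &&
          abs(config$stripped_dh_ph - ph_ref) > 1e-9) {
        th2 <- try_cell("thermal", paste0(lab, "@pH", config$stripped_dh_ph),
                        thermal_summary(rr, config$stripped_dh_ph, config))
        if (!is.null(th2)) {
          thermal[[paste0(lab, "_ph", config$stripped_dh_ph)]] <- th2
        }
      }
    } else {
      note("thermal", lab, sprintf(
        "needs exactly 2 temperatures, found %d; dH cells absent", length(rr)
      ))
    }
  }

  solubility <- if (!is.null(sol)) try_cell("solubility", id,
                                            fit_salting_out(sol))

  structure(
    list(
      hb_id = id,
      reference_ph = ph_ref,
      prenatal = prenatal,
      conditions = cond_rows,
      effects = effects,
      thermal = thermal,
      solubility = solubility,
      warnings = warnings,
      provenance = list(
        config_hash = config_hash(config),
        n_series = length(series),
        fitted = length(fits)
      )
    ),
    class = "hb_summary"
  )
}

# standardized n50 at the reference pH: regression of n50 on pH when >= 2
# distinct pH values exist, otherwise the plain mean
standardize_n50 <- function(fits, ph_ref) {
  ph <- vapply(fits, function(f) f$condition$ph, numeric(1))
  n50 <- vapply(fits, function(f) f$n50, numeric(1))
  if (length(unique(ph)) >= 2 && length(fits) >= 3) {
    fit <- stats::lm(n50 ~ ph)
    pr <- stats::predict(fit, newdata = data.frame(ph = ph_ref),
                         se.fit = TRUE)
    list(n50 = unname(pr$fit), se = unname(pr$se.fit))
  } else {
    list(n50 = mean(n50),
         se = if (length(n50) > 1) stats::sd(n50) / sqrt(length(n50))
              else NA_real_)
  }
}

#' @export
print.hb_summary <- function(x, ...) {
  cat(sprintf("<hb_summary> %s (reference pH %.2f%s)\n", x$hb_id,
              x$reference_ph, if (x$prenatal) ", prenatal" else ""))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  if (length(x$warnings) > 0) {
    cat(sprintf("  %d warning(s); see $warnings\n", length(x$warnings)))
  }
  invisible(x)
}

#' @export
as.data.frame.hb_summary <- function(x, ...) {
  rows <- lapply(x$conditions, function(cr) {
    tkey <- sprintf("%.6f", cr$temperature)
    eff <- x$effects[[tkey]]
    pick <- function(e) {
      if (is.null(e)) c(NA_real_, NA_real_) else c(e$delta_log_p50, e$se)
    }
    e_this <- if (!is.null(eff)) {
      switch(cr$condition_label,
             "DPG" = pick(eff$dpg_effect),
             "KCl" = pick(eff$cl_effect),
             "KCl+DPG" = pick(eff$combined_effect),
             c(NA_real_, NA_real_))
    } else {
      c(NA_real_, NA_real_)
    }
    th <- x$thermal[[cr$condition_label]]
    data.frame(
      hb_id = x$hb_id,
      condition = cr$condition_label,
      temp_c = kelvin_to_celsius(cr$temperature),
      reference_ph = x$reference_ph,
      p50 = cr$p50, se_p50 = cr$se_p50,
      n50 = cr$n50, se_n50 = cr$se_n50,
      bohr = cr$bohr, se_bohr = cr$se_bohr,
      effect_vs_stripped = e_this[1], se_effect = e_this[2],
      dh_raw = if (is.null(th)) NA_real_ else th$dh_raw,
      dh_corrected = if (is.null(th)) NA_real_ else th$dh_corrected,
      se_dh = if (is.null(th)) NA_real_ else th$se_dh,
      pct_precipitated_3M = if (is.null(x$solubility)) NA_real_ else
        x$solubility$percent_precipitated_at_3M,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition, out$temp_c), , drop = FALSE]
}

#' Compare hemoglobins against a baseline
#'
#' P50 ratios and log-scale differences per (condition, temperature) versus a
#' baseline hemoglobin, with SEs combined in log space by the delta method
#' (`se_log_ratio = sqrt(se_a^2 + se_b^2) / ln 10` on the log10 scale, ratio
#' SE `= ln(10) * ratio * se_log10_ratio`).
#'
#' @param summaries list of `hb_summary` from [run_pipeline()].
#' @param baseline_id `hb_id` of the baseline hemoglobin.
#' @return data frame with one row per (hb, condition, temperature) present in
#'   both the hemoglobin and the baseline: `p50_ratio`, `se_ratio`,
#'   `delta_log_p50`, `se_delta_log_p50`.
#' @export
compare_hbs <- function(summaries, baseline_id) {
  ids <- vapply(summaries, function(s) s$hb_id, character(1))
  if (!baseline_id %in% ids) {
    stop("baseline hemoglobin '", baseline_id, "' not found")
  }
  base <- as.data.frame(summaries[[match(baseline_id, ids)]])
  rows <- lapply(summaries, function(s) {
    df <- as.data.frame(s)
    j <- match(paste(df$condition, df$temp_c),
               paste(base$condition, base$temp_c))
    ok <- !is.na(j) & !is.na(df$p50) & !is.na(base$p50[j])
    df <- df[ok, , drop = FALSE]
    jb <- j[ok]
    se_log_a <- df$se_p50 / (log(10) * df$p50)
    se_log_b <- base$se_p50[jb] / (log(10) * base$p50[jb])
    se_dlog <- sqrt(se_log_a^2 + se_log_b^2)
    ratio <- df$p50 / base$p50[jb]
    data.frame(
      hb_id = df$hb_id, baseline = baseline_id,
      condition = df$condition, temp_c = df$temp_c,
      p50_ratio = ratio,
      se_ratio = log(10) * ratio * se_dlog,
      delta_log_p50 = log10(ratio),
      se_delta_log_p50 = se_dlog,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
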