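#' Read an oxygen-equilibrium measurement table
#'
#' Reads a CSV/TSV table with one row per equilibration and groups rows into
#' [oec_series()] objects by (sample, condition). Required columns:
#' `sample`, `ph`, `temp_c`, `kcl_M`, `heme_mM`, `po2_mmHg`, `saturation`,
#' plus exactly one DPG specification: `dpg_mM` (absolute molarity, mM) or
#' `dpg_fold` (fold molar excess over tetramer). An optional logical
#' `prenatal` column flags embryonic/fetal isoforms. The dialect is
#' comma-separated (tab for `.tsv`), header required, `.` decimal, UTF-8.
#'
#' Temperatures are stored in kelvin; concentrations in mol/L. Duplicate
#' (sample, condition, po2) rows are kept as independent observations.
#'
#' @param path path to the table.
#' @param config run configuration (unused fields are tolerated); present so
#'   that readers and the pipeline share one configuration object.
#' @return list of `oec_series`.
#' @export
read_oec_table <- function(path, config = default_config()) {
  df <- read_delim_table(path)
  required <- c("sample", "ph", "temp_c", "kcl_M", "heme_mM",
                "po2_mmHg", "saturation")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  has_dpg_m <- "dpg_mM" %in% names(df)
  has_dpg_f <- "dpg_fold" %in% names(df)
  if (has_dpg_m == has_dpg_f) {
    stop("exactly one of columns 'dpg_mM' or 'dpg_fold' must be present")
  }

  bad_sat <- which(!is.finite(df$saturation) |
                     df$saturation <= 0 | df$saturation >= 1)
  if (length(bad_sat) > 0) {
    stop("saturation outside (0,1) at data row(s) ",
         paste(bad_sat, collapse = ", "), " (logit undefined)")
  }
  bad_po2 <- which(!is.finite(df$po2_mmHg) | df$po2_mmHg <= 0)
  if (length(bad_po2) > 0) {
    stop("non-positive po2_mmHg at data row(s) ",
         paste(bad_po2, collapse = ", "))
  }

  prenatal <- if ("prenatal" %in% names(df)) {
    as.logical(df$prenatal)
  } else {
    rep(FALSE, nrow(df))
  }

  heme <- df$heme_mM * 1e-3
  dpg <- if (has_dpg_m) df$dpg_mM * 1e-3 else df$dpg_fold * heme / 4

  key <- paste(df$sample, signif(df$ph, 10), signif(df$temp_c, 10),
               signif(df$kcl_M, 10), signif(dpg, 10), signif(heme, 10),
               sep = "|")
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    i <- idx[1]
    cond <- condition(ph = df$ph[i], temp_c = df$temp_c[i], kcl = df$kcl_M[i],
                      dpg = dpg[i], heme_conc = heme[i])
    oec_series(df$sample[i], cond, df$po2_mmHg[idx], df$saturation[idx],
               prenatal = isTRUE(prenatal[i]))
  })
  unname(out[order(vapply(out, function(s) s$sample_id, character(1)))])
}

#' Read an ammonium-sulfate solubility table
#'
#' Columns: `sample`, `ammonium_sulfate_M`, `soluble_signal`. Rows are grouped
#' per sample and sorted by molarity; every sample must include a 0 M control
#' row. Duplicate molarities are retained as independent observations (a
#' message is emitted).
#'
#' @param path path to the CSV/TSV table.
#' @return list of [solubility_series()].
#' @export
read_solubility_table <- function(path) {
  df <- read_delim_table(path)
  required <- c("sample", "ammonium_sulfate_M", "soluble_signal")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  out <- lapply(split(seq_len(nrow(df)), df$sample), function(idx) {
    m <- df$ammonium_sulfate_M[idx]
    if (anyDuplicated(m)) {
      message("sample '", df$sample[idx[1]],
              "': duplicate molarity rows retained as replicates")
    }
    solubility_series(df$sample[idx[1]], m, df$soluble_signal[idx])
  })
  unname(out)
}

read_delim_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    check.names = FALSE)
}

#' Write the per-hemoglobin summary table
#'
#' Serializes a list of [run_pipeline()] summaries as a long CSV with one row
#' per (hemoglobin, condition, temperature): standardized P50 and n50 with
#' SEs, Bohr coefficient, effector effects, raw and corrected oxygenation
#' enthalpies, and percent precipitated at 3 M ammonium sulfate. Numbers are
#' written with 15 significant digits so a read-back reproduces them.
#'
#' @param summaries non-empty list of `hb_summary` objects.
#' @param path output CSV path.
#' @return (invisibly) the data frame written.
#' @export
write_summary_table <- function(summaries, path) {
  if (length(summaries) == 0) stop("empty summary list; nothing to write")
  df <- do.call(rbind, lapply(summaries, as.data.frame))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  fmt <- df
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) {
    ifelse(is.na(v), NA, sprintf("%.15g", v))
  })
  utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(df)
}

#' Write all fit objects as machine-readable JSON
#'
#' @param x a list (fits, regressions, summaries) of plain or classed lists.
#' @param path output path.
#' @export
write_fits_json <- function(x, path) {
  jsonlite::write_json(strip_classes(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}
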