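#' Default run configuration
#'
#' Central defaults for the analysis pipeline: reference pH values used for
#' standardizing P50 (7.20 for adult hemoglobins, 7.10 for prenatal isoforms,
#' reflecting the lower pH of prenatal blood), the pH window used for the Bohr
#' coefficient, the pair of assay temperatures, the gas constant, and the heat
#' of O2 solubilization subtracted from gas-tension-based van't Hoff
#' enthalpies.
#'
#' @return A named list with components:
#' \describe{
#'   \item{reference_ph_adult}{pH at which adult-Hb P50 is standardized (7.2).}
#'   \item{reference_ph_prenatal}{reference pH for embryonic/fetal isoforms (7.1).}
#'   \item{bohr_ph_range}{inclusive pH window for the Bohr slope, `c(6.9, 7.8)`.}
#'   \item{temperatures_c}{assay temperatures in degrees Celsius, `c(25, 37)`.}
#'   \item{gas_constant}{R in J mol-1 K-1 (8.314).}
#'   \item{solubilization_correction_kj}{heat of O2 solubilization, kJ mol-1 O2
#'     (12.55), added to the raw van't Hoff enthalpy.}
#'   \item{stripped_dh_ph}{additional reference pH (7.8) at which the
#'     stripped-Hb oxygenation enthalpy is reported, where oxygenation-linked
#'     proton binding is minimal.}
#'   \item{weight_by_se}{logical; inverse-variance weighting of the
#'     logP50-vs-pH regression by `se_log_p50^2` (default `FALSE`).}
#' }
#' @export
default_config <- function() {
  list(
    reference_ph_adult = 7.2,
    reference_ph_prenatal = 7.1,
    bohr_ph_range = c(6.9, 7.8),
    temperatures_c = c(25, 37),
    gas_constant = 8.314,
    solubilization_correction_kj = 12.55,
    stripped_dh_ph = 7.8,
    weight_by_se = FALSE
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Keys present in the file override the defaults of [default_config()];
#' unknown keys raise an error so that typos do not silently fall back to
#' defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a config list as in [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  )
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$reference_ph_adult), length(cfg$reference_ph_adult) == 1,
    is.numeric(cfg$reference_ph_prenatal),
    is.numeric(cfg$bohr_ph_range), length(cfg$bohr_ph_range) == 2,
    cfg$bohr_ph_range[1] < cfg$bohr_ph_range[2],
    is.numeric(cfg$temperatures_c),
    is.numeric(cfg$gas_constant), cfg$gas_constant > 0,
    is.numeric(cfg$solubilization_correction_kj)
  )
  cfg
}

# Stable short hash of a config (FNV-1a over its canonical JSON), recorded in
# outputs so a run can be tied to the exact configuration that produced it.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- fnv_step(h, b)
  sprintf("%08x", h)
}

fnv_step <- function(h, b) {
  # 32-bit FNV-1a step in double arithmetic (split multiply to stay exact)
  h <- bitwXor_dbl(h, b)
  lo <- h %% 65536
  hi <- h %/% 65536
  (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
}

# Noiseless (exactly collinear) inputs are legitimate here — synthetic and
# textbook data hit them routinely — so the stats warning about perfect fits
# is muffled; all other warnings pass through.
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}
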