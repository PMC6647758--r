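#' Default analysis configuration
#'
#' All thresholds, kinetic parameters, knowledge-based-module rules and
#' grading rules used by the pipeline, as a nested list. Every value can be
#' overridden via [read_config()] or by editing the returned list. Defaults
#' marked as rule-of-thumb or placeholder in the report metadata are exactly
#' the ones a clinic would be expected to recalibrate.
#'
#' @section Sections:
#' \describe{
#'   \item{metrics}{`bg_range` low/high (mmol/L) for time-in-range and event
#'     thresholds; `ea1c_gate` (`"strict"`: every day in the period needs the
#'     per-day minimum; `"mean"`: the mean daily count does); per-day and
#'     total gate counts; `isf_k` (100 or 85) for the insulin-sensitivity
#'     rule; `show_ea1c` display flag (hidden by default).}
#'   \item{kinetics}{bilinear insulin-activity parameters (`dia`, `peak`,
#'     minutes) per profile, `iob_curve` selector, carbohydrate absorption
#'     `carb_delay` (min) and `carb_rate` (g/h).}
#'   \item{smoothing}{moving-average `window` (registrations) and per-source
#'     weights.}
#'   \item{kbm}{plausibility bounds and thresholds for the five reliability
#'     criteria.}
#'   \item{events}{merge window, night window, severe-hypo threshold, blood
#'     pressure thresholds, cause-rule lookback windows (minutes).}
#'   \item{grading}{per-indicator green/orange intervals; indicators without
#'     a rule grade white.}
#' }
#'
#' @return nested configuration list of class `fullflow_config`.
#' @export
default_config <- function() {
  structure(list(
    timezone = "UTC",
    metrics = list(
      bg_range = c(low = 4.0, high = 10.0),   # mmol/L, from the 4-10 goal example
      ea1c_gate = "strict",
      ea1c_min_per_day = 3L,
      ea1c_min_total = 21L,
      isf_k = 100,                            # 100/85 rule numerator
      icr_k = 400,                            # 400 rule numerator
      show_ea1c = FALSE                       # hidden during the trial
    ),
    kinetics = list(
      iob_curve = "bilinear",
      bolus = list(dia = 180, peak = 75),     # minutes
      basal = list(dia = 180, peak = 75),
      carb_delay = 15,                        # minutes before absorption starts
      carb_rate = 30                          # g/hour linear absorption
    ),
    smoothing = list(
      window = 5L,
      weights = c(finger_prick = 2, cgm = 1), # finger prick twice the CGM weight
      default_weight = 1,
      series_min_per_day = 20,
      special_series_types = "blood_glucose"
    ),
    kbm = list(
      plausibility = list(
        blood_glucose  = c(1, 35),     # mmol/L
        weight         = c(20, 300),   # kg
        blood_pressure = c(60, 260),   # systolic mmHg
        heart_rate     = c(25, 250)    # /min
      ),
      max_error_fraction = 0.01,
      cross_source_window = 5,         # minutes
      cross_source_rel_diff = 0.5,
      bg_day_coverage = 0.7,
      regularity_factor = 2
    ),
    events = list(
      merge_window = 120,              # minutes between readings in one episode
      night = c(0, 6),                 # local hours defining "nocturnal"
      severe_hypo = 3.0,               # mmol/L
      bp_high = c(systolic = 140, diastolic = 90),
      lookback = c(bolus_without_meal = 120, activity_related = 180,
                   missed_bolus = 60)  # minutes
    ),
    grading = list(
      # green checked first, so shared boundaries grade to the better state
      mean_bg   = list(green = list(c(4, 8)),  orange = list(c(3.5, 4), c(8, 10))),
      tir_pct   = list(green = list(c(70, 100)), orange = list(c(50, 70))),
      systolic  = list(green = list(c(0, 130)), orange = list(c(130, 140))),
      diastolic = list(green = list(c(0, 85)),  orange = list(c(85, 90)))
    )
  ), class = "fullflow_config")
}

#' Read a configuration file
#'
#' Loads a YAML (or JSON) configuration and merges it over
#' [default_config()]: any key present in the file replaces the default,
#' everything else keeps its default value.
#'
#' @param path path to a YAML or JSON configuration file.
#' @return merged configuration list of class `fullflow_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  override <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configuration")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  structure(.merge_config(default_config(), override), class = "fullflow_config")
}

.merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- .merge_config(base[[key]], override[[key]])
    } else {
      value <- override[[key]]
      # restore names lost by YAML for named numeric vectors
      if (!is.null(base[[key]]) && !is.null(names(base[[key]])) &&
          is.null(names(value)) && length(value) == length(base[[key]])) {
        names(value) <- names(base[[key]])
      }
      base[[key]] <- value
    }
  }
  base
}

# 64-bit FNV-1a over a canonical JSON rendering; identifies a configuration
# in report metadata without a cryptographic-hash dependency.
.config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = 10, force = TRUE))
  h <- c(0xcbf29ce4, 0x84222325)  # two 32-bit halves
  prime_low <- 0x1b3
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep arithmetic in doubles
    h[2] <- h[2] - (h[2] %% 256) + bitwXor(h[2] %% 256, b)
    # multiply 64-bit (h) by 0x100000001b3 via 32-bit halves
    low <- h[2] * prime_low
    high <- h[1] * prime_low + h[2] + floor(low / 2^32)
    h <- c(high %% 2^32, low %% 2^32)
  }
  paste0(format(as.hexmode(h[1] %/% 16), width = 7),
         format(as.hexmode(h[1] %% 16), width = 1),
         format(as.hexmode(h[2] %/% 16), width = 7),
         format(as.hexmode(h[2] %% 16), width = 1))
}
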