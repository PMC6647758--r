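# Renderable data structures for the four graph sections: Combined Data,
# Daily Distribution (moving averages over the day-projected data), Daily
# Evolution (per-day aggregates) and Time Period (raw per-type series).
# These are data, not pixels: a front end can map them 1:1 onto charts.

#' Choose the graph representation for a data type
#'
#' Densely sampled types (at least `series_min_per_day` registrations per
#' day on average, 20 by default) and the special types (blood glucose)
#' render as continuous series; everything else renders as bars. Reference
#' ranges render as areas.
#'
#' @param n_records total registrations of the type.
#' @param n_days days in the collection period.
#' @param data_type the type.
#' @param config configuration list.
#' @return `"series"` or `"bars"`.
#' @export
classify_rendering <- function(n_records, n_days, data_type,
                               config = default_config()) {
  sm <- config$smoothing
  if (data_type %in% sm$special_series_types) return("series")
  if (n_days > 0 && n_records / n_days >= sm$series_min_per_day) {
    return("series")
  }
  "bars"
}

#' Trailing moving average with per-source weights
#'
#' Smooths an ordered sequence with a trailing window of up to
#' `config$smoothing$window` registrations (5 by default; the cap stops
#' dense CGM streams from drowning sparse finger-prick values). In
#' weighted mode each value is weighted by its collection source — a
#' finger-prick reading carries twice the weight of a CGM reading, since
#' test strips are more accurate than sensors needing calibration. With
#' `mode = "auto"` the weighted mean is used exactly when the sequence
#' mixes sources with distinct weights. The first points use all available
#' history, so the output aligns 1:1 with the input.
#'
#' @param values ordered numeric sequence.
#' @param sources character vector of sources parallel to `values` (only
#'   consulted in weighted mode).
#' @param config configuration list.
#' @param mode `"auto"`, `"simple"` or `"weighted"`.
#' @return numeric vector of the same length as `values`.
#' @export
moving_average <- function(values, sources = NULL,
                           config = default_config(), mode = "auto") {
  n <- length(values)
  if (n == 0L) return(numeric())
  sm <- config$smoothing
  window <- sm$window
  stopifnot(window >= 1)
  w_all <- rep(sm$default_weight, n)
  if (!is.null(sources)) {
    known <- sources %in% names(sm$weights)
    w_all[known] <- sm$weights[sources[known]]
  }
  weighted <- switch(mode,
    simple = FALSE,
    weighted = TRUE,
    auto = length(unique(w_all)) > 1L,
    stop("unknown moving-average mode: ", mode)
  )
  if (!weighted) w_all <- rep(1, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window + 1L)
    out[i] <- stats::weighted.mean(values[lo:i], w_all[lo:i])
  }
  out
}

.rendered_series <- function(data_type, representation, axis_unit, points,
                             reference_band = NULL, calculated = FALSE,
                             visible = TRUE) {
  structure(
    list(data_type = data_type, representation = representation,
         axis_unit = axis_unit, points = points,
         reference_band = reference_band, calculated = calculated,
         visible = visible),
    class = "rendered_series"
  )
}

#' @export
print.rendered_series <- function(x, ...) {
  cat("<rendered_series> ", x$data_type, " (", x$representation, ", ",
      x$axis_unit, "): ", nrow(x$points), " points",
      if (x$calculated) " [calculated]", "\n", sep = "")
  invisible(x)
}

.reference_band_of <- function(rec) {
  ok <- !is.na(rec$ref_low) & !is.na(rec$ref_high)
  if (!any(ok)) return(NULL)
  c(low = rec$ref_low[which(ok)[1]], high = rec$ref_high[which(ok)[1]])
}

#' Daily distribution of one data type
#'
#' Projects every registration of a type onto a single 24-hour axis
#' (time of day in the report timezone) to expose daily patterns such as
#' nocturnal lows, sorts by time of day (ties kept in original date
#' order), and smooths the projected sequence with [moving_average()].
#'
#' @param dataset a [patient_dataset()].
#' @param data_type data type to project.
#' @param config configuration list.
#' @return a `rendered_series` whose points carry `hour` (decimal hours),
#'   `value`, `source` and `ma` (the moving average).
#' @export
daily_distribution <- function(dataset, data_type,
                               config = default_config()) {
  rec <- dataset$records[dataset$records$data_type == data_type, ]
  if (nrow(rec) == 0L) {
    return(.rendered_series(data_type, "series",
                            canonical_unit(data_type),
                            data.frame(hour = numeric(), value = numeric(),
                                       source = character(),
                                       ma = numeric())))
  }
  secs <- as.numeric(format(rec$timestamp, tz = dataset$timezone, "%H")) * 3600 +
    as.numeric(format(rec$timestamp, tz = dataset$timezone, "%M")) * 60 +
    as.numeric(format(rec$timestamp, tz = dataset$timezone, "%S"))
  ord <- order(secs)                       # stable: ties stay in date order
  pts <- data.frame(hour = secs[ord] / 3600, value = rec$value[ord],
                    source = rec$source[ord], stringsAsFactors = FALSE)
  pts$ma <- moving_average(pts$value, pts$source, config)
  .rendered_series(data_type, "series", rec$unit[1], pts,
                   reference_band = .reference_band_of(rec))
}

# alternate distinct units over left/right axes in first-appearance order
.assign_axes <- function(units) {
  sides <- rep(c("left", "right"), length.out = length(units))
  data.frame(unit = units, side = sides, stringsAsFactors = FALSE)
}

#' Combined Data view
#'
#' All quantifiable data in one graph structure: one series or bar set per
#' data type plus the calculated insulin-on-board and carbohydrates-on-
#' board series. One vertical axis is created per distinct unit, assigned
#' alternately left/right in order of first appearance. Hiding a type is a
#' visibility flag on its series only — it never re-times other series.
#'
#' @param dataset a [patient_dataset()].
#' @param config configuration list.
#' @param kinetics optional precomputed result of the internal kinetic
#'   series builder; computed on demand when `NULL`.
#' @return list with `series` (list of `rendered_series`) and `axes`
#'   (`data.frame` of unit/side assignments).
#' @export
combined_view <- function(dataset, config = default_config(),
                          kinetics = NULL) {
  rec <- dataset$records
  n_days <- period_days(dataset)
  series <- list()
  for (tp in unique(rec$data_type)) {
    sub <- rec[rec$data_type == tp, ]
    rep_kind <- classify_rendering(nrow(sub), n_days, tp, config)
    pts <- data.frame(time = sub$timestamp, value = sub$value)
    if (tp == "blood_pressure") pts$value2 <- sub$value2
    series[[length(series) + 1L]] <-
      .rendered_series(tp, rep_kind, sub$unit[1], pts,
                       reference_band = .reference_band_of(sub))
  }
  if (is.null(kinetics)) kinetics <- .kinetic_series(dataset, config)
  if (nrow(kinetics$iob) > 0 && any(kinetics$iob$value > 0)) {
    series[[length(series) + 1L]] <-
      .rendered_series("insulin_on_board", "series", "U", kinetics$iob,
                       calculated = TRUE)
  }
  if (nrow(kinetics$cob) > 0 && any(kinetics$cob$value > 0)) {
    series[[length(series) + 1L]] <-
      .rendered_series("carbs_on_board", "series", "g", kinetics$cob,
                       calculated = TRUE)
  }
  units <- unique(vapply(series, function(s) s$axis_unit, character(1)))
  list(series = series, axes = .assign_axes(units))
}

#' Daily Evolution view
#'
#' One graph per data type, each the per-day aggregate of
#' [daily_aggregate()] (mean, sum, latest or count depending on the type).
#'
#' @param dataset a [patient_dataset()].
#' @param config configuration list.
#' @return list of `rendered_series`, one per type, with `day`/`value`
#'   points.
#' @export
daily_evolution_view <- function(dataset, config = default_config()) {
  lapply(unique(dataset$records$data_type), function(tp) {
    sub <- dataset$records[dataset$records$data_type == tp, ]
    .rendered_series(tp, "series", sub$unit[1], daily_aggregate(dataset, tp),
                     reference_band = .reference_band_of(sub))
  })
}

#' Time Period view
#'
#' The raw per-record series, one graph per data type, with no aggregation
#' or smoothing — the Combined Data content split out type by type.
#'
#' @param dataset a [patient_dataset()].
#' @param config configuration list.
#' @return list of `rendered_series` with `time`/`value` points.
#' @export
time_period_view <- function(dataset, config = default_config()) {
  n_days <- period_days(dataset)
  lapply(unique(dataset$records$data_type), function(tp) {
    sub <- dataset$records[dataset$records$data_type == tp, ]
    pts <- data.frame(time = sub$timestamp, value = sub$value)
    if (tp == "blood_pressure") pts$value2 <- sub$value2
    .rendered_series(tp, classify_rendering(nrow(sub), n_days, tp, config),
                     sub$unit[1], pts,
                     reference_band = .reference_band_of(sub))
  })
}
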