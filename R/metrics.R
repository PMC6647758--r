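# Overview-section scalar analytics: the data-summary table, pooled SD
# ("average deviation"), estimated A1c with gating, NGSP/IFCC conversion,
# rule-of-thumb insulin ratios, time in range and per-day aggregation.

# Aggregation mode per data type for the per-day views.
.agg_mode <- function(data_type) {
  if (data_type %in% c("blood_glucose", "heart_rate")) return("mean")
  if (data_type %in% c("insulin_bolus", "insulin_basal", "carbohydrate",
                       "calories", "physical_activity")) return("sum")
  if (data_type %in% c("weight", "blood_pressure")) return("latest")
  if (data_type == "medication") return("count")
  "mean"
}

#' Pooled standard deviation over daily groups
#'
#' Combines within-day sample variances across days using degrees-of-freedom
#' weights: \eqn{s_p = \sqrt{\sum_k (n_k - 1) s_k^2 / \sum_k (n_k - 1)}},
#' where \eqn{n_k} is the number of registrations on day \eqn{k} and
#' \eqn{s_k^2} that day's sample variance. Days with fewer than two
#' registrations carry no degrees of freedom and contribute nothing; days
#' with more registrations get a proportionally greater weight. This is the
#' dashboard's variability metric, surfaced to clinicians as the "average
#' deviation".
#'
#' @param values numeric measurement values.
#' @param days grouping vector (calendar day) parallel to `values`.
#' @return the pooled SD, or `NA` when no day has two or more values.
#' @export
pooled_sd <- function(values, days) {
  stopifnot(length(values) == length(days))
  groups <- split(values, days)
  n_k <- lengths(groups)
  keep <- n_k >= 2L
  if (!any(keep)) return(NA_real_)
  s2_k <- vapply(groups[keep], stats::var, numeric(1))
  w <- n_k[keep] - 1L
  sqrt(sum(w * s2_k) / sum(w))
}

#' Convert an NGSP A1c percentage to IFCC units
#'
#' Applies the IFCC-NGSP master equation
#' \eqn{\mathrm{IFCC} = 10.93 \cdot \mathrm{NGSP} - 23.50} (mmol/mol).
#' Both standards are reported because Norway switched from NGSP to IFCC
#' reporting in 2018 while most patient-facing material still uses percent.
#'
#' @param ngsp_pct A1c in NGSP percent.
#' @return A1c in IFCC mmol/mol.
#' @export
ngsp_to_ifcc <- function(ngsp_pct) 10.93 * ngsp_pct - 23.50

#' Estimate hemoglobin A1c from self-collected glucose
#'
#' Inverts the estimated-average-glucose regression
#' \eqn{eAG_{mmol/L} = 1.59 \cdot A_{1c} - 2.59} to predict A1c from the
#' mean of all blood glucose registrations. The estimate is gated: it is
#' only available with at least `ea1c_min_per_day` registrations per day
#' (under the default `"strict"` gate, on every day of the collection
#' period; under `"mean"`, on average) and at least `ea1c_min_total`
#' registrations in total. Sparse self-monitoring data simply cannot
#' support the estimate. The value is computed even when the `hidden`
#' display flag is set (the report carries it but marks it hidden).
#'
#' @param dataset a [patient_dataset()] (blood glucose in mmol/L).
#' @param config a [default_config()]-shaped configuration list.
#' @return object of class `a1c_estimate`: `ngsp_pct`, `ifcc_mmol_mol`,
#'   `mean_glucose`, `available`, `hidden`.
#' @export
estimate_a1c <- function(dataset, config = default_config()) {
  cfg <- config$metrics
  bg <- dataset$records[dataset$records$data_type == "blood_glucose", ]
  out <- structure(
    list(ngsp_pct = NA_real_, ifcc_mmol_mol = NA_real_,
         mean_glucose = NA_real_, available = FALSE,
         hidden = !isTRUE(cfg$show_ea1c)),
    class = "a1c_estimate"
  )
  if (nrow(bg) < cfg$ea1c_min_total) return(out)
  all_days <- .period_days(dataset)
  per_day <- table(factor(.record_days(bg$timestamp, dataset$timezone),
                          levels = as.character(all_days)))
  gate <- if (identical(cfg$ea1c_gate, "mean")) {
    mean(per_day) >= cfg$ea1c_min_per_day
  } else {
    all(per_day >= cfg$ea1c_min_per_day)
  }
  if (!gate) return(out)
  out$mean_glucose <- mean(bg$value)
  out$ngsp_pct <- (out$mean_glucose + 2.59) / 1.59
  out$ifcc_mmol_mol <- ngsp_to_ifcc(out$ngsp_pct)
  out$available <- TRUE
  out
}

#' @export
print.a1c_estimate <- function(x, ...) {
  if (!x$available) {
    cat("eA1c: not available (gating not satisfied)\n")
  } else {
    cat(sprintf("eA1c: %.1f%% NGSP / %.0f mmol/mol IFCC (mean glucose %.2f mmol/L)%s\n",
                x$ngsp_pct, x$ifcc_mmol_mol, x$mean_glucose,
                if (x$hidden) " [hidden]" else ""))
  }
  invisible(x)
}

#' Rule-of-thumb insulin ratios
#'
#' Total daily dose (TDD, mean of the daily basal+bolus sums over days with
#' insulin data), the insulin sensitivity factor by the 100/85 rule
#' (`isf_k / TDD`, mmol/L per U; `isf_k` defaults to 100), the
#' insulin-to-carbohydrate ratio by the 400 rule (`400 / TDD`, g per U),
#' and the basal:bolus ratio. These are population rules of thumb, not
#' individualized therapy parameters, and the report flags them as such.
#' All values are `NA` when the dataset has no insulin records.
#'
#' @param dataset a [patient_dataset()].
#' @param config configuration list.
#' @return object of class `derived_ratios` with `tdd`,
#'   `insulin_sensitivity`, `icr`, `basal_bolus_ratio`, and
#'   `patient_reported` (placeholder, `NULL` unless supplied upstream).
#' @export
derived_ratios <- function(dataset, config = default_config()) {
  rec <- dataset$records
  ins <- rec[rec$data_type %in% c("insulin_bolus", "insulin_basal"), ]
  out <- structure(
    list(tdd = NA_real_, insulin_sensitivity = NA_real_, icr = NA_real_,
         basal_bolus_ratio = NA_real_, patient_reported = NULL),
    class = "derived_ratios"
  )
  if (nrow(ins) == 0L) return(out)
  day <- .record_days(ins$timestamp, dataset$timezone)
  daily <- tapply(ins$value, day, sum)
  tdd <- mean(daily)
  if (tdd <= 0) return(out)
  out$tdd <- tdd
  out$insulin_sensitivity <- config$metrics$isf_k / tdd
  out$icr <- config$metrics$icr_k / tdd
  basal <- sum(ins$value[ins$data_type == "insulin_basal"])
  bolus <- sum(ins$value[ins$data_type == "insulin_bolus"])
  out$basal_bolus_ratio <- if (bolus > 0) basal / bolus else NA_real_
  out
}

#' @export
print.derived_ratios <- function(x, ...) {
  if (is.na(x$tdd)) {
    cat("insulin ratios: not available (no insulin data)\n")
    return(invisible(x))
  }
  cat(sprintf("TDD %.1f U/day | ISF %.2f mmol/L per U | I:C %.1f g/U | basal:bolus %.2f\n",
              x$tdd, x$insulin_sensitivity, x$icr, x$basal_bolus_ratio))
  invisible(x)
}

#' Three-level time-in-range partition
#'
#' Partitions blood glucose readings into low / in range / high against a
#' closed target interval: a reading equal to either bound counts as in
#' range.
#'
#' @param values numeric glucose readings (mmol/L).
#' @param range `c(low, high)` target interval, `low < high`.
#' @return object of class `range_summary` with integer `counts`, `percents`
#'   (`NA` when there are no readings) and the `range` used.
#' @export
time_in_range <- function(values, range = c(4, 10)) {
  stopifnot(range[1] < range[2])
  counts <- c(low = sum(values < range[1]),
              in_range = sum(values >= range[1] & values <= range[2]),
              high = sum(values > range[2]))
  n <- sum(counts)
  percents <- if (n > 0) 100 * counts / n else
    c(low = NA_real_, in_range = NA_real_, high = NA_real_)
  structure(list(counts = counts, percents = percents,
                 range = c(low = range[1], high = range[2])),
            class = "range_summary")
}

#' @export
print.range_summary <- function(x, ...) {
  cat(sprintf("BG range [%.1f, %.1f] mmol/L: low %d (%.1f%%) | in range %d (%.1f%%) | high %d (%.1f%%)\n",
              x$range[1], x$range[2],
              x$counts[1], x$percents[1], x$counts[2], x$percents[2],
              x$counts[3], x$percents[3]))
  invisible(x)
}

#' Aggregate one data type per calendar day
#'
#' Applies the type's daily aggregation rule: glucose and heart rate are
#' averaged, amounts (insulin, carbohydrate, calories, activity minutes)
#' are summed, weight and blood pressure keep the latest registration of
#' the day, and medication is counted.
#'
#' @param dataset a [patient_dataset()].
#' @param data_type data type to aggregate.
#' @return `data.frame` with `day` (Date), `value` and, for blood pressure,
#'   `value2` (diastolic); zero rows when the type is absent.
#' @export
daily_aggregate <- function(dataset, data_type) {
  rec <- dataset$records[dataset$records$data_type == data_type, ]
  if (nrow(rec) == 0L) {
    return(data.frame(day = as.Date(character()), value = numeric()))
  }
  day <- .record_days(rec$timestamp, dataset$timezone)
  mode <- .agg_mode(data_type)
  if (mode == "latest") {
    # records are time-ordered, so the last row per day is the latest
    idx <- tapply(seq_len(nrow(rec)), day, function(i) i[length(i)])
    out <- data.frame(day = as.Date(names(idx)), value = rec$value[idx])
    if (data_type == "blood_pressure") out$value2 <- rec$value2[idx]
    rownames(out) <- NULL
    return(out)
  }
  agg <- switch(mode,
    mean = tapply(rec$value, day, mean),
    sum = tapply(rec$value, day, sum),
    count = tapply(rec$value, day, length)
  )
  data.frame(day = as.Date(names(agg)), value = as.numeric(agg),
             row.names = NULL)
}

#' Overview data-summary table
#'
#' One row per data type present in the dataset: total registrations,
#' average registrations per day over the collection period, mean value,
#' pooled SD ("average deviation"; omitted for blood pressure and
#' medication, where only the latest or a count per day is meaningful), and
#' the latest value with its timestamp. For blood pressure the mean and
#' latest refer to the systolic component.
#'
#' @param dataset a [patient_dataset()].
#' @param config configuration list.
#' @return `data.frame` of class `summary_table`; zero rows for an empty
#'   dataset.
#' @export
summary_table <- function(dataset, config = default_config()) {
  rec <- dataset$records
  types <- unique(rec$data_type)
  n_days <- period_days(dataset)
  rows <- lapply(types, function(tp) {
    sub <- rec[rec$data_type == tp, ]
    day <- .record_days(sub$timestamp, dataset$timezone)
    sd_ok <- !tp %in% c("blood_pressure", "medication")
    last <- sub[nrow(sub), ]
    data.frame(
      data_type = tp,
      n_total = nrow(sub),
      avg_per_day = nrow(sub) / n_days,
      mean_value = mean(sub$value),
      average_deviation = if (sd_ok) pooled_sd(sub$value, day) else NA_real_,
      latest_value = last$value,
      latest_time = last$timestamp,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    data_type = character(), n_total = integer(), avg_per_day = numeric(),
    mean_value = numeric(), average_deviation = numeric(),
    latest_value = numeric(), latest_time = as.POSIXct(character(), tz = "UTC")
  )
  class(out) <- c("summary_table", "data.frame")
  out
}

# overview "average daily values": mean of the per-day aggregates, per type
.daily_averages <- function(dataset) {
  types <- unique(dataset$records$data_type)
  vals <- vapply(types, function(tp) mean(daily_aggregate(dataset, tp)$value),
                 numeric(1))
  data.frame(data_type = types, daily_average = as.numeric(vals),
             stringsAsFactors = FALSE)
}

# overview "latest values": last registration per type
.latest_values <- function(dataset) {
  rec <- dataset$records
  types <- unique(rec$data_type)
  rows <- lapply(types, function(tp) {
    sub <- rec[rec$data_type == tp, ]
    last <- sub[nrow(sub), ]
    data.frame(data_type = tp, value = last$value, value2 = last$value2,
               unit = last$unit, timestamp = last$timestamp,
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else data.frame(
    data_type = character(), value = numeric(), value2 = numeric(),
    unit = character(), timestamp = as.POSIXct(character(), tz = "UTC"))
}
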