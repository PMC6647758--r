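# Four-state color grading and assembly of the six-section report
# document. The report is the deliverable: a deterministic, serializable
# tree a dashboard front end renders directly.

#' Grade a value into one of four color states
#'
#' Green: in the recommended range. Orange: slightly outside it. Red: out
#' of range. White: the indicator has no grading rule (no accepted
#' standard, or the value depends too heavily on context — e.g. the daily
#' amount of insulin). Green intervals are checked before orange, so a
#' shared boundary grades to the better state.
#'
#' @param indicator rule name (e.g. `"mean_bg"`, `"tir_pct"`,
#'   `"systolic"`).
#' @param value numeric value to grade.
#' @param rules grading rules (`config$grading`).
#' @return one of `"green"`, `"orange"`, `"red"`, `"white"`.
#' @export
grade_value <- function(indicator, value, rules = default_config()$grading) {
  rule <- rules[[indicator]]
  if (is.null(rule) || is.na(value)) return("white")
  inside <- function(intervals) {
    any(vapply(intervals, function(iv) value >= iv[1] && value <= iv[2],
               logical(1)))
  }
  if (inside(rule$green)) return("green")
  if (inside(rule$orange)) return("orange")
  "red"
}

#' Data List section
#'
#' One row per registration — date, data type, value (plus diastolic for
#' blood pressure), unit and comment — together with the total
#' registration count.
#'
#' @param dataset a [patient_dataset()].
#' @return object of class `data_list`: `count` and `rows` (`data.frame`
#'   ordered by date).
#' @export
data_list <- function(dataset) {
  rec <- dataset$records
  rows <- data.frame(
    date = format(rec$timestamp, tz = dataset$timezone,
                  format = "%Y-%m-%d %H:%M:%S"),
    data_type = rec$data_type,
    value = rec$value,
    value2 = rec$value2,
    unit = rec$unit,
    comment = ifelse(is.na(rec$comment), "", rec$comment),
    stringsAsFactors = FALSE
  )
  structure(list(count = nrow(rows), rows = rows), class = "data_list")
}

#' Build the full six-section report
#'
#' Runs every analytic module over the dataset and assembles the report
#' document: Overview (reliability, data summary, insulin ratios,
#' estimated A1c, glucose summary, time in range, daily averages, latest
#' values, color grades, personal goals, noticeable events and their
#' weekday/hour distribution), Combined Data, Daily Distribution, Daily
#' Evolution, Time Period and Data List. Goals precede noticeable events
#' so patients can steer the consultation. The estimated A1c is always
#' computed but carries `hidden = TRUE` under the default configuration.
#' The document is a pure function of dataset and configuration —
#' `meta$generated_at` is the period end, not the wall clock — so
#' identical inputs produce byte-identical JSON.
#'
#' @param dataset a [patient_dataset()] (from [read_fhir_bundle()] or
#'   [generate_scenario()]).
#' @param config configuration list.
#' @return object of class `fullflow_report`.
#' @export
fullflow_report <- function(dataset, config = default_config()) {
  stopifnot(inherits(dataset, "patient_dataset"))
  rec <- dataset$records
  bg <- rec[rec$data_type == "blood_glucose", ]
  rng <- config$metrics$bg_range
  empty <- nrow(rec) == 0L

  reliability <- grade_reliability(dataset, config)
  summary_tab <- summary_table(dataset, config)
  ratios <- derived_ratios(dataset, config)
  ea1c <- estimate_a1c(dataset, config)
  rng_summary <- time_in_range(bg$value, rng)
  bg_summary <- list(
    mean = if (nrow(bg)) mean(bg$value) else NA_real_,
    average_deviation = if (nrow(bg)) {
      pooled_sd(bg$value, .record_days(bg$timestamp, dataset$timezone))
    } else NA_real_
  )
  events <- detect_events(dataset, config)
  goals <- lapply(dataset$goals, goal_progress, dataset = dataset)
  kin <- .kinetic_series(dataset, config)

  latest <- .latest_values(dataset)
  grades <- list(
    mean_bg = grade_value("mean_bg", bg_summary$mean, config$grading),
    tir_pct = grade_value("tir_pct", rng_summary$percents[["in_range"]],
                          config$grading),
    ea1c = grade_value("ea1c", ea1c$ngsp_pct, config$grading),
    tdd = grade_value("tdd", ratios$tdd, config$grading)
  )
  if ("blood_pressure" %in% latest$data_type) {
    bp_last <- latest[latest$data_type == "blood_pressure", ]
    grades$systolic <- grade_value("systolic", bp_last$value, config$grading)
    grades$diastolic <- grade_value("diastolic", bp_last$value2,
                                    config$grading)
  }

  overview <- list(
    reliability = reliability,
    data_summary = summary_tab,
    ratios = ratios,
    ea1c = ea1c,
    bg_summary = bg_summary,
    range_summary = rng_summary,
    daily_averages = .daily_averages(dataset),
    latest_values = latest,
    grades = grades,
    goals = goals,
    noticeable_events = events,
    event_distribution = distribute_events(events, dataset$timezone)
  )

  meta <- list(
    schema_version = "1.0",
    generated_at = if (empty) NA_character_ else
      .format_instant(dataset$period[["end"]]),
    config_hash = .config_hash(config),
    timezone = dataset$timezone,
    period = if (empty) list(start = NULL, end = NULL, days = 0L,
                             no_data = TRUE) else
      list(start = .format_instant(dataset$period[["start"]]),
           end = .format_instant(dataset$period[["end"]]),
           days = period_days(dataset), no_data = FALSE),
    rule_of_thumb = c("insulin_sensitivity", "icr"),
    grading_rules_are_defaults = TRUE
  )

  structure(
    list(
      meta = meta,
      overview = overview,
      combined = combined_view(dataset, config, kinetics = kin),
      daily_distribution = lapply(
        stats::setNames(nm = unique(rec$data_type)),
        function(tp) daily_distribution(dataset, tp, config)),
      daily_evolution = daily_evolution_view(dataset, config),
      time_period = time_period_view(dataset, config),
      data_list = data_list(dataset)
    ),
    class = "fullflow_report"
  )
}

#' @export
print.fullflow_report <- function(x, ...) {
  p <- x$meta$period
  cat("FullFlow report (schema ", x$meta$schema_version, ")\n", sep = "")
  if (isTRUE(p$no_data)) {
    cat("  period: no data\n")
  } else {
    cat("  period: ", p$start, " .. ", p$end, " (", p$days, " days)\n",
        sep = "")
  }
  print(x$overview$reliability)
  cat("  events: ", length(x$overview$noticeable_events), " noticeable\n",
      sep = "")
  invisible(x)
}

#' @export
summary.fullflow_report <- function(object, ...) {
  x <- object
  print(x)
  cat("\nData summary:\n")
  print(as.data.frame(x$overview$data_summary))
  cat("\n")
  print(x$overview$ratios)
  print(x$overview$range_summary)
  if (x$overview$ea1c$available && !x$overview$ea1c$hidden) {
    print(x$overview$ea1c)
  }
  kinds <- table(vapply(x$overview$noticeable_events,
                        function(e) e$kind, character(1)))
  if (length(kinds)) {
    cat("\nNoticeable events:\n")
    for (k in names(kinds)) cat("  ", k, ": ", kinds[[k]], "\n", sep = "")
  }
  invisible(x)
}

# recursive conversion to JSON-friendly structures: classed lists are
# unclassed, named atomic vectors become objects, data frames and matrices
# pass through
.jsonable <- function(x) {
  if (is.data.frame(x) || is.matrix(x)) return(x)
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, .jsonable))
  }
  if (is.atomic(x) && !is.null(names(x)) && length(x) > 1L) {
    return(lapply(stats::setNames(as.list(unname(x)), names(x)), identity))
  }
  x
}

#' Serialize a report to JSON
#'
#' Deterministic JSON rendering: timestamps are ISO 8601 UTC, numbers keep
#' 10 significant digits, and the output bytes are a pure function of the
#' dataset and configuration that produced the report.
#'
#' @param report a [fullflow_report()].
#' @param path optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(.jsonable(report), auto_unbox = TRUE, digits = 10,
                           POSIXt = "ISO8601", UTC = TRUE, na = "null",
                           null = "null", pretty = TRUE, force = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

# required keys per report section; the shipped JSON description in
# inst/extdata mirrors this
.report_schema <- list(
  top = c("meta", "overview", "combined", "daily_distribution",
          "daily_evolution", "time_period", "data_list"),
  meta = c("schema_version", "generated_at", "config_hash", "timezone",
           "period"),
  overview = c("reliability", "data_summary", "ratios", "ea1c",
               "bg_summary", "range_summary", "daily_averages",
               "latest_values", "grades", "goals", "noticeable_events",
               "event_distribution")
)

#' Validate a report document's structure
#'
#' Checks the six-section contract: all sections present, required meta
#' and overview keys present, and every grade one of the four color
#' states.
#'
#' @param report a [fullflow_report()] (or a parsed report JSON list).
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_report <- function(report) {
  miss <- setdiff(.report_schema$top, names(report))
  if (length(miss)) stop("report missing sections: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(.report_schema$meta, names(report$meta))
  if (length(miss)) stop("report meta missing: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(.report_schema$overview, names(report$overview))
  if (length(miss)) stop("report overview missing: ",
                         paste(miss, collapse = ", "))
  grades <- unlist(report$overview$grades)
  bad <- setdiff(grades, c("green", "orange", "red", "white"))
  if (length(bad)) stop("invalid color grades: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
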