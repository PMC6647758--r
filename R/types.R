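#' @keywords internal
"_PACKAGE"

# Canonical data types and their units. `other` types carry their own code
# and unit through untouched.
.data_types <- c("blood_glucose", "insulin_bolus", "insulin_basal",
                 "carbohydrate", "calories", "physical_activity", "weight",
                 "blood_pressure", "heart_rate", "medication")

.canonical_units <- c(
  blood_glucose     = "mmol/L",
  insulin_bolus     = "U",
  insulin_basal     = "U",
  carbohydrate      = "g",
  calories          = "kcal",
  physical_activity = "min",
  weight            = "kg",
  blood_pressure    = "mm[Hg]",
  heart_rate        = "/min",
  medication        = "1"
)

.sources <- c("finger_prick", "cgm", "pump", "pen", "manual", "unknown")

#' Canonical unit for a data type
#'
#' @param data_type character vector of data type names.
#' @return UCUM unit strings; `NA` for unregistered (`other:`) types.
#' @export
canonical_unit <- function(data_type) {
  out <- unname(.canonical_units[data_type])
  out
}

#' Construct a single observation record
#'
#' One timestamped self-collected measurement. Blood pressure carries a
#' systolic/diastolic pair: `value` holds the systolic and `value2` the
#' diastolic component, both in mmHg.
#'
#' @param id opaque identifier string.
#' @param timestamp `POSIXct` instant (stored in UTC internally).
#' @param data_type one of the registered types
#'   (blood_glucose, insulin_bolus, insulin_basal, carbohydrate, calories,
#'   physical_activity, weight, blood_pressure, heart_rate, medication) or
#'   `"other:<code>"` for an unregistered code.
#' @param value numeric measurement value (systolic for blood pressure).
#' @param value2 diastolic value for blood pressure, otherwise `NA`.
#' @param unit UCUM unit string; defaults to the type's canonical unit.
#' @param source collection source: finger_prick, cgm, pump, pen, manual or
#'   unknown.
#' @param ref_low,ref_high optional reference range in value units.
#' @param comment optional free-text note.
#' @return a one-row `data.frame` in the internal record layout.
#' @export
observation_record <- function(id, timestamp, data_type, value, value2 = NA_real_,
                               unit = NULL, source = "unknown",
                               ref_low = NA_real_, ref_high = NA_real_,
                               comment = NA_character_) {
  stopifnot(inherits(timestamp, "POSIXct"), length(value) == 1L)
  if (!is.finite(value)) stop("observation value must be finite")
  registered <- data_type %in% .data_types
  if (!registered && !startsWith(data_type, "other:")) {
    stop("unknown data_type: ", data_type)
  }
  if (is.null(unit)) {
    unit <- if (registered) .canonical_units[[data_type]] else NA_character_
  }
  if (!source %in% .sources) stop("unknown source: ", source)
  if (!is.na(ref_low) && !is.na(ref_high) && !(ref_low < ref_high)) {
    stop("reference range must satisfy low < high")
  }
  data.frame(
    id = as.character(id),
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    data_type = data_type,
    value = as.numeric(value),
    value2 = as.numeric(value2),
    unit = as.character(unit),
    source = source,
    ref_low = as.numeric(ref_low),
    ref_high = as.numeric(ref_high),
    comment = as.character(comment),
    stringsAsFactors = FALSE
  )
}

.empty_records <- function() {
  data.frame(
    id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    data_type = character(), value = numeric(), value2 = numeric(),
    unit = character(), source = character(), ref_low = numeric(),
    ref_high = numeric(), comment = character(), stringsAsFactors = FALSE
  )
}

#' Construct a personal goal
#'
#' Goals are either measurable (a metric plus a target range, e.g. keeping
#' blood glucose between 4 and 10 mmol/L) or purely descriptive.
#'
#' @param description free-text goal description.
#' @param measurable logical; measurable goals must carry `metric` and
#'   `target`.
#' @param metric data type the goal refers to, for measurable goals.
#' @param target numeric `c(low, high)` target range, for measurable goals.
#' @return an object of class `personal_goal`.
#' @export
personal_goal <- function(description, measurable = FALSE, metric = NULL,
                          target = NULL) {
  if (measurable && (is.null(metric) || is.null(target))) {
    stop("measurable goals require a metric and a target range")
  }
  if (!is.null(target)) {
    stopifnot(length(target) == 2L, target[1] < target[2])
  }
  structure(
    list(description = description, measurable = isTRUE(measurable),
         metric = metric, target = if (is.null(target)) NULL else unname(target)),
    class = "personal_goal"
  )
}

#' Assemble a patient dataset
#'
#' Orders records by timestamp (stable on ties) and derives the collection
#' period from the first and last record.
#'
#' @param records a record `data.frame` (rows from [observation_record()],
#'   row-bound).
#' @param goals list of [personal_goal()] objects.
#' @param timezone IANA timezone used to define the calendar day for all
#'   daily aggregation (default `"UTC"`).
#' @return an object of class `patient_dataset` with elements `records`,
#'   `goals`, `period` (`POSIXct` start/end, or `NULL` when empty) and
#'   `timezone`.
#' @export
patient_dataset <- function(records = .empty_records(), goals = list(),
                            timezone = "UTC") {
  if (nrow(records) > 0) {
    ord <- order(records$timestamp)   # order() is stable
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
    period <- c(start = min(records$timestamp), end = max(records$timestamp))
  } else {
    period <- NULL
  }
  structure(
    list(records = records, goals = goals, period = period,
         timezone = timezone),
    class = "patient_dataset"
  )
}

#' @export
print.patient_dataset <- function(x, ...) {
  n <- nrow(x$records)
  cat("<patient_dataset> ", n, " records, ", length(x$goals), " goals\n",
      sep = "")
  if (n > 0) {
    cat("  period: ", format(x$period[["start"]], tz = x$timezone), " to ",
        format(x$period[["end"]], tz = x$timezone), " (", x$timezone, ")\n",
        sep = "")
    tab <- sort(table(x$records$data_type), decreasing = TRUE)
    cat("  types:  ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  no data\n")
  }
  invisible(x)
}

#' @export
print.personal_goal <- function(x, ...) {
  cat("<personal_goal> ", x$description, "\n", sep = "")
  if (x$measurable) {
    cat("  measurable: ", x$metric, " in [", x$target[1], ", ", x$target[2],
        "]\n", sep = "")
  }
  invisible(x)
}

# Calendar day (as Date) of each timestamp under the dataset timezone.
.record_days <- function(timestamps, timezone) {
  as.Date(format(timestamps, tz = timezone, format = "%Y-%m-%d"))
}

# All calendar days spanned by the collection period (inclusive).
.period_days <- function(dataset) {
  if (is.null(dataset$period)) return(as.Date(character()))
  seq(.record_days(dataset$period[["start"]], dataset$timezone),
      .record_days(dataset$period[["end"]], dataset$timezone), by = "day")
}

#' Number of calendar days in the collection period
#'
#' @param dataset a `patient_dataset`.
#' @return integer day count (0 for an empty dataset).
#' @export
period_days <- function(dataset) length(.period_days(dataset))
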