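# Knowledge-based grading of data reliability, noticeable-event detection
# with rule-based causes, event distribution, and goal progress. The five
# reliability criteria (presence, value errors, cross-source consistency,
# registration counts, regularity) follow the knowledge-based-module
# design; every threshold is a config default a clinic can retune.

# fixed total severity order, rank 1 = most serious
.severity <- c(nocturnal_hypoglycemia = 1L, hypoglycemia = 2L,
               hyperglycemia = 3L, high_blood_pressure = 4L,
               missed_medication = 5L)

#' Grade the reliability of a patient dataset
#'
#' Evaluates five criteria and grades the dataset `reliable` only when all
#' pass: \emph{presence} (any data at all), \emph{value_errors} (at most a
#' small fraction of records outside physiological plausibility bounds),
#' \emph{cross_source} (no near-simultaneous glucose readings from the
#' patient that disagree wildly), \emph{counts} (glucose registered on
#' enough of the collection days) and \emph{regularity} (no registration
#' gap far out of line with a type's usual cadence). A not-reliable grade
#' comes with the list of failed findings so the clinician knows whether
#' the data are worth consulting.
#'
#' @param dataset a [patient_dataset()].
#' @param config configuration list (`config$kbm` thresholds).
#' @return object of class `reliability_report`: `grade`
#'   (`"reliable"`/`"not_reliable"`) and `findings` (`data.frame` with
#'   `criterion`, `passed`, `message`).
#' @export
grade_reliability <- function(dataset, config = default_config()) {
  kbm <- config$kbm
  rec <- dataset$records
  findings <- list()
  note <- function(criterion, passed, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      criterion = criterion, passed = passed, message = message,
      stringsAsFactors = FALSE)
  }

  note("presence", nrow(rec) > 0,
       if (nrow(rec) > 0) sprintf("%d records present", nrow(rec))
       else "no registered data")

  bounded <- names(kbm$plausibility)
  in_scope <- rec[rec$data_type %in% bounded, ]
  if (nrow(in_scope) > 0) {
    bad <- mapply(function(tp, v) {
      b <- kbm$plausibility[[tp]]
      v < b[1] | v > b[2]
    }, in_scope$data_type, in_scope$value)
    frac <- mean(bad)
    note("value_errors", frac < kbm$max_error_fraction,
         sprintf("%.2f%% of bounded-type values outside plausibility bounds",
                 100 * frac))
  } else {
    note("value_errors", TRUE, "no bounded-type values to check")
  }

  bg <- rec[rec$data_type == "blood_glucose", ]
  cross_ok <- TRUE
  if (nrow(bg) >= 2) {
    dt <- diff(as.numeric(bg$timestamp)) / 60
    rel <- abs(diff(bg$value)) / pmax(bg$value[-1], bg$value[-nrow(bg)])
    cross_ok <- !any(dt <= kbm$cross_source_window &
                       rel > kbm$cross_source_rel_diff)
  }
  note("cross_source", cross_ok,
       if (cross_ok) "no conflicting near-simultaneous glucose readings"
       else "near-simultaneous glucose readings disagree by more than 50%")

  days <- .period_days(dataset)
  coverage <- if (length(days) > 0) {
    length(unique(.record_days(bg$timestamp, dataset$timezone))) / length(days)
  } else 0
  note("counts", coverage >= kbm$bg_day_coverage,
       sprintf("glucose registered on %.0f%% of collection days",
               100 * coverage))

  reg_ok <- TRUE
  irregular <- character()
  for (tp in unique(rec$data_type)) {
    ts <- as.numeric(rec$timestamp[rec$data_type == tp])
    if (length(ts) < 3) next
    gaps <- diff(sort(ts))
    if (max(gaps) > kbm$regularity_factor * stats::median(gaps) + 86400) {
      reg_ok <- FALSE
      irregular <- c(irregular, tp)
    }
  }
  note("regularity", reg_ok,
       if (reg_ok) "registration cadence is regular"
       else paste("irregular registration gaps for:",
                  paste(irregular, collapse = ", ")))

  findings <- do.call(rbind, findings)
  structure(
    list(grade = if (all(findings$passed)) "reliable" else "not_reliable",
         findings = findings),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("data reliability: ", x$grade, "\n", sep = "")
  bad <- x$findings[!x$findings$passed, ]
  if (nrow(bad) > 0) {
    for (i in seq_len(nrow(bad))) {
      cat("  issue [", bad$criterion[i], "]: ", bad$message[i], "\n", sep = "")
    }
  }
  invisible(x)
}

.new_event <- function(kind, start, end, peak_value, ids) {
  structure(
    list(kind = kind, severity_rank = .severity[[kind]], start = start,
         end = end, peak_value = peak_value, causes = character(),
         supporting_record_ids = ids),
    class = "noticeable_event"
  )
}

#' @export
print.noticeable_event <- function(x, ...) {
  cat("<event> ", x$kind, " ", format(x$start), " .. ", format(x$end),
      " (peak ", x$peak_value, ")", sep = "")
  if (length(x$causes)) cat("  causes:", paste(x$causes, collapse = ", "))
  cat("\n")
  invisible(x)
}

# merge threshold-crossing readings into maximal episodes: a new reading
# joins the current episode when it follows within the merge window
.episodes <- function(times, values, ids, peak_fn, merge_sec) {
  if (length(times) == 0L) return(list())
  out <- list()
  run <- 1L
  for (i in seq_along(times)[-1]) {
    if (as.numeric(times[i]) - as.numeric(times[i - 1]) < merge_sec) {
      run <- c(run, i)
    } else {
      out[[length(out) + 1L]] <- run
      run <- i
    }
  }
  out[[length(out) + 1L]] <- run
  lapply(out, function(idx) list(
    start = times[idx[1]], end = times[idx[length(idx)]],
    peak = peak_fn(values[idx]), ids = ids[idx]
  ))
}

#' Detect noticeable events
#'
#' Scans the dataset for clinically salient episodes: hypoglycemia
#' (glucose below the low threshold; graded nocturnal when the episode
#' midpoint falls in the night window), hyperglycemia (above the high
#' threshold), high blood pressure (systolic/diastolic at or above the
#' configured limits) and missed medication (a calendar day with zero
#' medication records although the patient's modal daily count is at least
#' one). Consecutive out-of-range readings separated by less than the
#' merge window form one episode, so episodes of one kind never overlap.
#' Events are sorted most-serious-first, then by start time, and causes
#' are attached via [attach_causes()].
#'
#' @param dataset a [patient_dataset()].
#' @param config configuration list (`config$events` thresholds).
#' @param causes logical; attach rule-based causes (default `TRUE`).
#' @return list of `noticeable_event` objects.
#' @export
detect_events <- function(dataset, config = default_config(),
                          causes = TRUE) {
  ev_cfg <- config$events
  rng <- config$metrics$bg_range
  rec <- dataset$records
  events <- list()
  add <- function(e) events[[length(events) + 1L]] <<- e
  merge_sec <- ev_cfg$merge_window * 60

  bg <- rec[rec$data_type == "blood_glucose", ]
  low_idx <- bg$value < rng[["low"]]
  for (ep in .episodes(bg$timestamp[low_idx], bg$value[low_idx],
                       bg$id[low_idx], min, merge_sec)) {
    mid <- ep$start + (as.numeric(ep$end) - as.numeric(ep$start)) / 2
    mid_h <- as.numeric(format(mid, tz = dataset$timezone, "%H")) +
      as.numeric(format(mid, tz = dataset$timezone, "%M")) / 60
    kind <- if (mid_h >= ev_cfg$night[1] && mid_h < ev_cfg$night[2]) {
      "nocturnal_hypoglycemia"
    } else "hypoglycemia"
    add(.new_event(kind, ep$start, ep$end, ep$peak, ep$ids))
  }
  high_idx <- bg$value > rng[["high"]]
  for (ep in .episodes(bg$timestamp[high_idx], bg$value[high_idx],
                       bg$id[high_idx], max, merge_sec)) {
    add(.new_event("hyperglycemia", ep$start, ep$end, ep$peak, ep$ids))
  }

  bp <- rec[rec$data_type == "blood_pressure", ]
  hi <- bp$value >= ev_cfg$bp_high[["systolic"]] |
    bp$value2 >= ev_cfg$bp_high[["diastolic"]]
  for (ep in .episodes(bp$timestamp[hi], bp$value[hi], bp$id[hi], max,
                       merge_sec)) {
    add(.new_event("high_blood_pressure", ep$start, ep$end, ep$peak, ep$ids))
  }

  med <- rec[rec$data_type == "medication", ]
  if (nrow(med) > 0) {
    all_days <- .period_days(dataset)
    per_day <- table(factor(.record_days(med$timestamp, dataset$timezone),
                            levels = as.character(all_days)))
    counts <- as.integer(per_day)
    modal <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
    if (modal >= 1L) {
      for (d in all_days[counts == 0L]) {
        day_start <- as.POSIXct(paste(as.Date(d, origin = "1970-01-01"),
                                      "00:00:00"), tz = dataset$timezone)
        add(.new_event("missed_medication", day_start, day_start + 86399,
                       0, character()))
      }
    }
  }

  ord <- order(vapply(events, function(e) e$severity_rank, integer(1)),
               vapply(events, function(e) as.numeric(e$start), numeric(1)))
  events <- events[ord]
  if (causes) events <- lapply(events, attach_causes, dataset = dataset,
                               config = config)
  events
}

#' Attach rule-based potential causes to an event
#'
#' Fires simple lookback rules: a hypoglycemic episode preceded (within 2
#' hours) by an insulin bolus with no carbohydrate record in between gets
#' `"bolus_without_meal"`; one preceded (within 3 hours) by physical
#' activity gets `"activity_related"`; a hyperglycemic episode preceded
#' (within 1 hour) by carbohydrate intake with no bolus gets
#' `"missed_bolus"`. An empty cause list is a valid outcome.
#'
#' @param event a `noticeable_event`.
#' @param dataset the dataset the event was detected from.
#' @param config configuration list (`config$events$lookback`, minutes).
#' @return the event with its `causes` filled in.
#' @export
attach_causes <- function(event, dataset, config = default_config()) {
  lb <- config$events$lookback
  rec <- dataset$records
  t0 <- as.numeric(event$start)
  within <- function(types, minutes) {
    ts <- as.numeric(rec$timestamp[rec$data_type %in% types])
    ts[ts >= t0 - minutes * 60 & ts < t0]
  }
  causes <- character()
  if (event$kind %in% c("hypoglycemia", "nocturnal_hypoglycemia")) {
    boluses <- within("insulin_bolus", lb[["bolus_without_meal"]])
    if (length(boluses) > 0) {
      carbs <- within("carbohydrate", lb[["bolus_without_meal"]])
      if (length(carbs) == 0L) causes <- c(causes, "bolus_without_meal")
    }
    if (length(within("physical_activity", lb[["activity_related"]])) > 0) {
      causes <- c(causes, "activity_related")
    }
  }
  if (event$kind == "hyperglycemia") {
    carbs <- within("carbohydrate", lb[["missed_bolus"]])
    if (length(carbs) > 0 &&
        length(within("insulin_bolus", lb[["missed_bolus"]])) == 0L) {
      causes <- c(causes, "missed_bolus")
    }
  }
  event$causes <- causes
  event
}

#' Distribute events over weekday and hour
#'
#' Counts each event once at its start instant into a 7 x 24 weekday-by-
#' hour grid (Monday first) plus a per-kind tally, exposing weekly and
#' daily trends such as a night-time cluster of hypoglycemia.
#'
#' @param events list of `noticeable_event` objects.
#' @param timezone timezone defining weekday and hour.
#' @return object of class `event_distribution`: `by_kind` (named counts)
#'   and `grid` (7 x 24 integer matrix).
#' @export
distribute_events <- function(events, timezone = "UTC") {
  grid <- matrix(0L, nrow = 7, ncol = 24,
                 dimnames = list(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat",
                                   "Sun"), 0:23))
  by_kind <- integer(0)
  for (e in events) {
    wd <- as.integer(format(e$start, tz = timezone, "%u"))
    hr <- as.integer(format(e$start, tz = timezone, "%H"))
    grid[wd, hr + 1L] <- grid[wd, hr + 1L] + 1L
    by_kind[e$kind] <- (if (e$kind %in% names(by_kind)) by_kind[[e$kind]]
                        else 0L) + 1L
  }
  structure(list(by_kind = by_kind, grid = grid),
            class = "event_distribution")
}

#' Progress on a personal goal
#'
#' Measurable goals report the fraction of the goal metric's readings that
#' fall inside the target range (systolic component for blood pressure);
#' nonmeasurable goals carry their description only.
#'
#' @param goal a [personal_goal()].
#' @param dataset a [patient_dataset()].
#' @return list with `description` and, for measurable goals with at least
#'   one matching reading, `progress` in `[0, 1]`.
#' @export
goal_progress <- function(goal, dataset) {
  out <- list(description = goal$description)
  if (!goal$measurable) return(out)
  vals <- dataset$records$value[dataset$records$data_type == goal$metric]
  if (length(vals) == 0L) return(out)
  out$progress <- mean(vals >= goal$target[1] & vals <= goal$target[2])
  out
}
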