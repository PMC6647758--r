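# Seeded scenario generator. Three clinically motivated scenarios drive the
# whole test surface:
#   1. type 1 diabetes, finger pricks + insulin pen, nightly hypoglycemia;
#   2. type 1 diabetes, CGM + pump, post-meal hyper/hypo "yoyo" excursions;
#   3. type 2 diabetes, sparse logging, high fasting glucose, high blood
#      pressure, occasionally missed medication.
# Daily registration counts are exact (10/4/6/1, 288/24/5, 1/2/5 plus the
# sparse whole-period extras) so fixture counts are assertable; "per day on
# average" collapses to "per day exactly".

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

# vectorized record builder (observation_record() is per-row and too slow
# for CGM-sized outputs)
.make_records <- function(timestamp, data_type, value, value2 = NA_real_,
                          unit = NULL, source = "unknown",
                          ref_low = NA_real_, ref_high = NA_real_,
                          comment = NA_character_) {
  n <- length(timestamp)
  if (is.null(unit)) unit <- canonical_unit(data_type)
  data.frame(
    id = rep("", n), timestamp = as.POSIXct(timestamp, tz = "UTC"),
    data_type = rep_len(data_type, n), value = as.numeric(value),
    value2 = rep_len(as.numeric(value2), n), unit = rep_len(unit, n),
    source = rep_len(source, n), ref_low = rep_len(as.numeric(ref_low), n),
    ref_high = rep_len(as.numeric(ref_high), n),
    comment = rep_len(as.character(comment), n), stringsAsFactors = FALSE
  )
}

#' Reference measurable personal goal
#'
#' The canonical measurable goal used throughout the test fixtures: keeping
#' blood glucose between 4 and 10 mmol/L.
#'
#' @return a measurable [personal_goal()].
#' @export
generate_goal_fixture <- function() {
  personal_goal("Keep blood glucose between 4 and 10 mmol/L",
                measurable = TRUE, metric = "blood_glucose",
                target = c(4, 10))
}

#' Generate a synthetic patient dataset for a scenario
#'
#' Produces a deterministic, seeded dataset reproducing one of the three
#' study scenarios. Identical arguments yield identical datasets (and hence
#' byte-identical serialized bundles). Clinical patterns (nightly
#' hypoglycemia, post-meal excursions, high fasting glucose, missed
#' medication) are layered on by [inject_patterns()], which is called
#' automatically unless `patterns = FALSE`.
#'
#' @param scenario integer 1, 2 or 3.
#' @param days number of collection days (default: 30 for scenario 1, 7 for
#'   scenario 2, 14 for scenario 3 — the appointment horizons of the three
#'   scenarios).
#' @param seed integer RNG seed; the generator restores the caller's RNG
#'   state.
#' @param patterns logical; apply [inject_patterns()] (default `TRUE`).
#' @param timezone report timezone (default UTC).
#' @return a [patient_dataset()] whose per-day record counts are exact:
#'   scenario 1 — 10 blood glucose (finger prick), 4 carbohydrate, 2 basal +
#'   4 bolus insulin, 1 physical activity; scenario 2 — 288 CGM glucose, 24
#'   hourly boluses, 5 carbohydrate; scenario 3 — 1 glucose, 2 medication
#'   (one deliberately missed day), 5 calories, plus 2 weight, 1 blood
#'   pressure and 3 short physical activities over the whole period.
#' @export
generate_scenario <- function(scenario, days = NULL, seed = 1L,
                              patterns = TRUE, timezone = "UTC") {
  stopifnot(scenario %in% 1:3)
  if (is.null(days)) days <- c(30L, 7L, 14L)[scenario]
  if (days < 1) stop("days must be >= 1")
  start <- as.POSIXct("2024-03-04 00:00:00", tz = timezone)  # a Monday
  ds <- .with_seed(seed, switch(scenario,
    .scenario1(start, days),
    .scenario2(start, days),
    .scenario3(start, days)
  ))
  ds$timezone <- timezone
  if (patterns) ds <- inject_patterns(ds, scenario, seed = seed)
  ds$records$id <- sprintf("s%d-%05d", scenario, seq_len(nrow(ds$records)))
  ds
}

.at <- function(start, day, hh, mm = 0) start + day * 86400 + hh * 3600 + mm * 60

.scenario1 <- function(start, days) {
  bg_times <- list(c(2, 30), c(7, 0), c(9, 0), c(11, 30), c(13, 30),
                   c(16, 30), c(18, 0), c(20, 0), c(21, 30), c(23, 0))
  # post-meal readings sit a little higher than pre-meal ones
  bg_mean <- c(4.8, 6.2, 8.0, 6.2, 8.0, 6.8, 6.2, 8.0, 7.0, 6.5)
  bg_sd <- c(0.3, rep(0.7, 9))
  meal <- list(c(7, 30, 40), c(12, 0, 50), c(18, 15, 60), c(21, 0, 20))
  rows <- vector("list", days)
  for (d in seq_len(days) - 1L) {
    bg_ts <- vapply(seq_along(bg_times), function(i) {
      jitter <- if (i == 1) 0 else round(stats::runif(1, -10, 10))
      as.numeric(.at(start, d, bg_times[[i]][1], bg_times[[i]][2] + jitter))
    }, numeric(1))
    bg_val <- pmin(pmax(stats::rnorm(10, bg_mean, bg_sd), 1.8), 20)
    carbs_ts <- vapply(meal, function(m) as.numeric(.at(start, d, m[1], m[2])),
                       numeric(1))
    carbs_g <- vapply(meal, function(m) m[3] + round(stats::runif(1, -10, 10)),
                      numeric(1))
    bolus_u <- round(stats::runif(4, 4, 8) * 2) / 2
    rows[[d + 1L]] <- rbind(
      .make_records(.POSIXct(bg_ts, tz = "UTC"), "blood_glucose", bg_val,
                    source = "finger_prick", ref_low = 4, ref_high = 10),
      .make_records(.POSIXct(carbs_ts, tz = "UTC"), "carbohydrate", carbs_g,
                    source = "manual"),
      .make_records(c(.at(start, d, 8), .at(start, d, 22)), "insulin_basal",
                    c(12, 12), source = "pen"),
      .make_records(.POSIXct(carbs_ts + 300, tz = "UTC"), "insulin_bolus",
                    bolus_u, source = "pen"),
      .make_records(.at(start, d, 17), "physical_activity", 10,
                    source = "manual", comment = "walk")
    )
  }
  patient_dataset(do.call(rbind, rows),
                  goals = list(generate_goal_fixture(),
                               personal_goal("Avoid night-time lows")))
}

.scenario2 <- function(start, days) {
  meal_hours <- c(7, 10.5, 13, 16.5, 19)
  rows <- vector("list", days)
  for (d in seq_len(days) - 1L) {
    grid <- .at(start, d, 0) + seq(0, 86100, by = 300)      # 288 points
    hours <- (as.numeric(grid) - as.numeric(.at(start, d, 0))) / 3600
    baseline <- 5.8 + 0.6 * sin(2 * pi * (hours - 16) / 24)
    bg <- pmin(pmax(baseline + stats::rnorm(288, 0, 0.15), 1.8), 25)
    meal_ts <- vapply(meal_hours, function(h) {
      as.numeric(.at(start, d, floor(h), (h %% 1) * 60))
    }, numeric(1))
    grams <- round(stats::runif(5, 30, 80))
    bolus_ts <- vapply(0:23, function(h) as.numeric(.at(start, d, h)),
                       numeric(1))
    bolus_u <- round(stats::runif(24, 0.8, 1.2), 1)
    at_meal <- floor(meal_hours) + 1L                       # hourly slot index
    bolus_u[at_meal] <- bolus_u[at_meal] + round(stats::runif(5, 3, 6), 1)
    rows[[d + 1L]] <- rbind(
      .make_records(grid, "blood_glucose", bg, source = "cgm",
                    ref_low = 4, ref_high = 10),
      .make_records(.POSIXct(meal_ts, tz = "UTC"), "carbohydrate", grams,
                    source = "manual"),
      .make_records(.POSIXct(bolus_ts, tz = "UTC"), "insulin_bolus", bolus_u,
                    source = "pump")
    )
  }
  patient_dataset(do.call(rbind, rows),
                  goals = list(generate_goal_fixture(),
                               personal_goal("Improve carbohydrate counting")))
}

.scenario3 <- function(start, days) {
  cal <- list(c(7, 30, 400), c(12, 0, 700), c(15, 0, 300), c(18, 30, 800),
              c(21, 0, 250))
  rows <- vector("list", days)
  for (d in seq_len(days) - 1L) {
    cal_ts <- vapply(cal, function(m) as.numeric(.at(start, d, m[1], m[2])),
                     numeric(1))
    cal_kcal <- vapply(cal, function(m) m[3] + round(stats::runif(1, -50, 50)),
                       numeric(1))
    rows[[d + 1L]] <- rbind(
      .make_records(.at(start, d, 7), "blood_glucose",
                    stats::rnorm(1, 9.3, 0.3), source = "finger_prick",
                    ref_low = 4, ref_high = 10),
      .make_records(c(.at(start, d, 8), .at(start, d, 20)), "medication",
                    c(1, 1), source = "manual", comment = "metformin"),
      .make_records(.POSIXct(cal_ts, tz = "UTC"), "calories", cal_kcal,
                    source = "manual")
    )
  }
  # sparse whole-period registrations
  last <- days - 1L
  pa_days <- unique(pmin(last, round(last * c(0.2, 0.5, 0.8))))
  extras <- rbind(
    .make_records(c(.at(start, 0L, 9), .at(start, last, 21)), "weight",
                  c(92.0, 91.4), source = "manual"),
    .make_records(.at(start, min(last, max(0L, days %/% 3)), 10),
                  "blood_pressure", 126, value2 = 81, source = "manual",
                  ref_low = 90, ref_high = 140),
    .make_records(.POSIXct(vapply(rep_len(pa_days, 3), function(d)
                    as.numeric(.at(start, d, 17)), numeric(1)) +
                    c(0, 600, 1200), tz = "UTC"),
                  "physical_activity", round(stats::runif(3, 5, 9)),
                  source = "manual")
  )
  patient_dataset(rbind(do.call(rbind, rows), extras),
                  goals = list(generate_goal_fixture(),
                               personal_goal("Remember my medication")))
}

#' Inject scenario-specific clinical patterns
#'
#' Overlays the clinical signature of each scenario onto a baseline dataset
#' from [generate_scenario()]: scenario 1 gets a nocturnal hypoglycemic
#' reading on 90\% of days; scenario 2 gets a post-meal "yoyo" excursion
#' (rise above the high threshold, then a dip below the low threshold) after
#' 4 of 5 daily meals; scenario 3 gets high fasting glucose on 90\% of days,
#' elevated blood pressure, and one day with all medication registrations
#' missing. Day selection is deterministic (day index modulo 10) so the
#' pattern frequency holds for every seed.
#'
#' @param dataset a baseline `patient_dataset` from
#'   `generate_scenario(..., patterns = FALSE)`.
#' @param scenario scenario id (1, 2 or 3).
#' @param seed RNG seed for the pattern magnitudes.
#' @return the modified `patient_dataset`.
#' @export
inject_patterns <- function(dataset, scenario, seed = 0L) {
  stopifnot(scenario %in% 1:3)
  .with_seed(seed + 1000L * scenario, {
    rec <- dataset$records
    day0 <- .record_days(dataset$period[["start"]], dataset$timezone)
    dayidx <- as.integer(.record_days(rec$timestamp, dataset$timezone) - day0)
    hour <- as.numeric(format(rec$timestamp, tz = dataset$timezone, "%H")) +
      as.numeric(format(rec$timestamp, tz = dataset$timezone, "%M")) / 60
    if (scenario == 1) {
      for (d in unique(dayidx)) {
        if (d %% 10 == 9) next
        night <- which(rec$data_type == "blood_glucose" & dayidx == d &
                         hour >= 0 & hour < 6)
        if (length(night)) {
          rec$value[night[1]] <- round(stats::runif(1, 2.8, 3.4), 1)
        }
      }
    } else if (scenario == 2) {
      bg <- which(rec$data_type == "blood_glucose")
      meals <- which(rec$data_type == "carbohydrate")
      # response curves in (minutes after meal, delta mmol/L)
      yoyo <- list(x = c(0, 45, 90, 150, 210), y = c(0, 6.5, 1.0, -2.6, 0))
      mild <- list(x = c(0, 45, 120), y = c(0, 2.5, 0))
      for (d in unique(dayidx[meals])) {
        day_meals <- meals[dayidx[meals] == d]
        for (k in seq_along(day_meals)) {
          curve <- if (k %% 5 == 2) mild else yoyo   # 4 of 5 meals "yoyo"
          m_t <- as.numeric(rec$timestamp[day_meals[k]])
          dmin <- (as.numeric(rec$timestamp[bg]) - m_t) / 60
          hit <- which(dmin > 0 & dmin < max(curve$x))
          if (length(hit)) {
            delta <- stats::approx(curve$x, curve$y, dmin[hit], rule = 2)$y
            rec$value[bg[hit]] <- pmax(rec$value[bg[hit]] + delta, 1.8)
          }
        }
      }
    } else {
      for (d in unique(dayidx)) {
        if (d %% 10 == 9) next
        fasting <- which(rec$data_type == "blood_glucose" & dayidx == d)
        if (length(fasting)) {
          rec$value[fasting[1]] <- round(stats::runif(1, 10.8, 12.2), 1)
        }
      }
      bp <- which(rec$data_type == "blood_pressure")
      rec$value[bp] <- 148
      rec$value2[bp] <- 95
      missed_day <- max(dayidx) %/% 2
      drop <- which(rec$data_type == "medication" & dayidx == missed_day)
      if (length(drop)) rec <- rec[-drop, , drop = FALSE]
    }
    rownames(rec) <- NULL
    dataset$records <- rec
    dataset
  })
}
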