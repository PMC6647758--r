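# knowledge-based reliability grading, event detection, causes,
# distribution, goal progress

test_that("an empty dataset is not reliable, failing the presence criterion", {
  rep <- grade_reliability(patient_dataset())
  expect_equal(rep$grade, "not_reliable")
  f <- rep$findings
  expect_false(f$passed[f$criterion == "presence"])
  expect_equal(sort(f$criterion),
               sort(c("presence", "value_errors", "cross_source", "counts",
                      "regularity")))
})

test_that("a clean scenario-1 dataset passes all five criteria", {
  rep <- grade_reliability(generate_scenario(1, days = 14, seed = 8))
  expect_equal(rep$grade, "reliable")
  expect_true(all(rep$findings$passed))
})

test_that("an implausible glucose value fails the value-errors criterion", {
  ds <- make_bg_dataset(7, 3, values = 6.5)
  ds$records$value[5] <- 99           # far outside the 1-35 mmol/L bounds
  rep <- grade_reliability(ds)
  f <- rep$findings
  expect_false(f$passed[f$criterion == "value_errors"])
  expect_equal(rep$grade, "not_reliable")
})

test_that("near-simultaneous disagreeing glucose readings fail cross-source consistency", {
  t0 <- as.POSIXct("2024-03-04 08:00:00", tz = "UTC")
  rows <- rbind(
    observation_record("a", t0, "blood_glucose", 5.0, source = "finger_prick"),
    observation_record("b", t0 + 120, "blood_glucose", 12.0, source = "cgm"),
    observation_record("c", t0 + 7200, "blood_glucose", 6.0)
  )
  rep <- grade_reliability(patient_dataset(rows))
  f <- rep$findings
  expect_false(f$passed[f$criterion == "cross_source"])
})

test_that("sparse glucose coverage fails the counts criterion", {
  ds <- make_bg_dataset(10, 3)
  keep <- ds$records$timestamp < as.POSIXct("2024-03-08", tz = "UTC")
  rec <- ds$records[keep, ]
  # stretch the period with a non-glucose record at the end
  rec <- rbind(rec, observation_record(
    "w", as.POSIXct("2024-03-13 09:00:00", tz = "UTC"), "weight", 80))
  rep <- grade_reliability(patient_dataset(rec))
  f <- rep$findings
  expect_false(f$passed[f$criterion == "counts"])
})

test_that("adding regular in-range records never flips reliable to not reliable", {
  ds <- generate_scenario(1, days = 10, seed = 12)
  expect_equal(grade_reliability(ds)$grade, "reliable")
  extra <- make_bg_dataset(10, 2, values = 6.0)$records
  extra$id <- paste0("extra-", seq_len(nrow(extra)))
  grown <- patient_dataset(rbind(ds$records, extra), goals = ds$goals)
  expect_equal(grade_reliability(grown)$grade, "reliable")
})

test_that("no out-of-range reading means no glycemic events", {
  expect_length(detect_events(make_bg_dataset(3, 4, values = 6.5)), 0L)
})

test_that("a short run of low readings merges into one nocturnal event", {
  t0 <- as.POSIXct("2024-03-04 02:00:00", tz = "UTC")
  rows <- rbind(
    observation_record("a", t0, "blood_glucose", 3.5),
    observation_record("b", t0 + 1800, "blood_glucose", 3.2),
    observation_record("c", t0 + 6 * 3600, "blood_glucose", 6.0)
  )
  ev <- detect_events(patient_dataset(rows))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$kind, "nocturnal_hypoglycemia")
  expect_equal(ev[[1]]$peak_value, 3.2)
  expect_equal(ev[[1]]$supporting_record_ids, c("a", "b"))
})

test_that("readings separated by more than the merge window form separate events", {
  t0 <- as.POSIXct("2024-03-04 10:00:00", tz = "UTC")
  rows <- rbind(
    observation_record("a", t0, "blood_glucose", 3.5),
    observation_record("b", t0 + 3 * 3600, "blood_glucose", 3.4)
  )
  ev <- detect_events(patient_dataset(rows))
  expect_length(ev, 2L)
  expect_true(all(event_kinds(ev) == "hypoglycemia"))
})

test_that("events are sorted most-serious-first and never overlap within a kind", {
  ds <- generate_scenario(2, days = 3, seed = 14)
  ev <- detect_events(ds)
  ranks <- vapply(ev, function(e) e$severity_rank, integer(1))
  expect_true(!is.unsorted(ranks))
  for (k in unique(event_kinds(ev))) {
    same <- ev[event_kinds(ev) == k]
    if (length(same) < 2) next
    same <- same[order(vapply(same, function(e) as.numeric(e$start),
                              numeric(1)))]
    for (i in seq_along(same)[-1]) {
      expect_gt(as.numeric(same[[i]]$start), as.numeric(same[[i - 1]]$end))
    }
  }
})

test_that("scenario 3 yields high blood pressure and missed-medication events", {
  ev <- detect_events(generate_scenario(3, days = 14, seed = 3))
  expect_gte(sum(event_kinds(ev) == "high_blood_pressure"), 1L)
  expect_equal(sum(event_kinds(ev) == "missed_medication"), 1L)
})

test_that("cause rules fire on their lookback windows", {
  t0 <- as.POSIXct("2024-03-04 03:00:00", tz = "UTC")
  # hypo at 03:00 with a bolus at 01:30 and no carbs
  rows <- rbind(
    observation_record("b", t0 - 90 * 60, "insulin_bolus", 6, source = "pen"),
    observation_record("g", t0, "blood_glucose", 3.1)
  )
  ev <- detect_events(patient_dataset(rows))
  expect_true("bolus_without_meal" %in% ev[[1]]$causes)
  # the same bolus with a meal alongside does not fire the rule
  rows2 <- rbind(rows, observation_record(
    "c", t0 - 85 * 60, "carbohydrate", 40))
  ev2 <- detect_events(patient_dataset(rows2))
  expect_false("bolus_without_meal" %in% ev2[[1]]$causes)
  # physical activity within 3 h marks the hypo activity-related
  rows3 <- rbind(
    observation_record("p", t0 - 150 * 60, "physical_activity", 45),
    observation_record("g", t0, "blood_glucose", 3.1)
  )
  ev3 <- detect_events(patient_dataset(rows3))
  expect_true("activity_related" %in% ev3[[1]]$causes)
  # hyper 30 min after a 60 g meal with no bolus
  rows4 <- rbind(
    observation_record("c", t0, "carbohydrate", 60),
    observation_record("g", t0 + 30 * 60, "blood_glucose", 13.0)
  )
  ev4 <- detect_events(patient_dataset(rows4))
  expect_true("missed_bolus" %in% ev4[[1]]$causes)
})

test_that("an event with an empty lookback has no causes", {
  ds <- patient_dataset(rec1("2024-03-04 03:00:00", "blood_glucose", 3.1))
  ev <- detect_events(ds)
  expect_length(ev[[1]]$causes, 0L)
})

test_that("event distribution bins events at their start and conserves counts", {
  expect_equal(sum(distribute_events(list())$grid), 0L)
  t0 <- as.POSIXct("2024-03-04 02:10:00", tz = "UTC")   # a Monday
  rows <- do.call(rbind, lapply(0:2, function(i) {
    observation_record(paste0("g", i), t0 + i * 7200, "blood_glucose",
                       3.2 + i %% 2 / 10)
  }))
  ev <- detect_events(patient_dataset(rows))
  dist <- distribute_events(ev)
  expect_equal(sum(dist$grid), length(ev))
  expect_equal(sum(dist$by_kind), length(ev))
  expect_gte(dist$grid["Mon", "2"], 1L)
})

test_that("goal progress is the in-target fraction; nonmeasurable goals have none", {
  g <- generate_goal_fixture()
  ds <- make_bg_dataset(1, 4, values = c(3.2, 5.0, 9.9, 12.1))
  expect_equal(goal_progress(g, ds)$progress, 0.5)
  soft <- personal_goal("be more proactive")
  expect_null(goal_progress(soft, ds)$progress)
  # measurable goal with no matching readings: description only
  wg <- personal_goal("keep weight down", measurable = TRUE,
                      metric = "weight", target = c(70, 85))
  expect_null(goal_progress(wg, ds)$progress)
})
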