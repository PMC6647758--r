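# summary metrics: pooled SD, eA1c, conversions, ratios, time in range,
# daily aggregation, summary table

# independent from-definition oracle: per-day sample variances combined
# with degrees-of-freedom weights
pooled_sd_oracle <- function(values, days) {
  num <- 0; den <- 0
  for (d in unique(days)) {
    v <- values[days == d]
    if (length(v) >= 2) {
      num <- num + (length(v) - 1) * var(v)
      den <- den + (length(v) - 1)
    }
  }
  if (den == 0) NA_real_ else sqrt(num / den)
}

test_that("pooled SD reproduces hand-computed cases", {
  # two days with identical unit SDs pool to 1
  expect_equal(pooled_sd(c(4, 6, 8, 10) / sqrt(2), c(1, 1, 2, 2)), 1.0)
  # one qualifying day degenerates to that day's sample SD
  expect_equal(pooled_sd(c(4, 6), c(1, 1)), sd(c(4, 6)))
  # day1 {4,6} (s2=2), day2 {8,10,12} (s2=4): sqrt((1*2 + 2*4)/3)
  expect_equal(pooled_sd(c(4, 6, 8, 10, 12), c(1, 1, 2, 2, 2)),
               sqrt(10 / 3), tolerance = 1e-12)
})

test_that("pooled SD is absent (not zero) when no day has two values", {
  expect_true(is.na(pooled_sd(c(4, 7, 9), c(1, 2, 3))))
})

test_that("pooled SD matches the from-definition oracle on random groupings", {
  set.seed(404)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    days <- sample(1:8, n, replace = TRUE)
    values <- rnorm(n, 7, 2)
    expect_equal(pooled_sd(values, days), pooled_sd_oracle(values, days),
                 tolerance = 1e-9)
  }
})

test_that("pooled SD ignores day order and single-registration days", {
  set.seed(7)
  values <- rnorm(12); days <- rep(1:3, each = 4)
  base <- pooled_sd(values, days)
  perm <- sample(seq_along(values))
  expect_equal(pooled_sd(values[perm], days[perm]), base)
  expect_equal(pooled_sd(c(values, 99), c(days, 4)), base)
})

test_that("eA1c inverts the published eAG regression when gates pass", {
  ds <- make_bg_dataset(7, 3, values = 7.0)
  a <- estimate_a1c(ds)
  expect_true(a$available)
  expect_equal(a$ngsp_pct, (7.0 + 2.59) / 1.59, tolerance = 1e-9)
  ds10 <- make_bg_dataset(7, 3, values = 10.0)
  expect_equal(estimate_a1c(ds10)$ngsp_pct, (10.0 + 2.59) / 1.59,
               tolerance = 1e-9)
  expect_equal(estimate_a1c(ds10)$ngsp_pct, 7.918, tolerance = 1e-3)
})

test_that("eA1c gating: both total and per-day thresholds bind", {
  # 20 readings in total: below the total gate
  expect_false(estimate_a1c(make_bg_dataset(5, 4))$available)
  # 22 readings but a day below the per-day gate under the strict reading
  ds <- make_bg_dataset(7, 3)
  ds$records <- ds$records[-2, ]
  ds <- patient_dataset(ds$records)
  expect_false(estimate_a1c(ds)$available)
  # under the mean gate the same dataset passes (mean 20/7 < 3 fails; use 22/7 >= 3)
  cfg <- default_config()
  cfg$metrics$ea1c_gate <- "mean"
  ds2 <- make_bg_dataset(7, 3)
  ds2$records <- rbind(ds2$records[-2, ], ds2$records[1, ][rep(1, 2), ])
  ds2 <- patient_dataset(ds2$records)
  expect_true(estimate_a1c(ds2, cfg)$available)
})

test_that("eA1c availability is monotone in added readings", {
  ds <- make_bg_dataset(7, 3, values = 7)
  expect_true(estimate_a1c(ds)$available)
  extra <- make_bg_dataset(7, 2, values = 8)$records
  extra$id <- paste0("x", seq_len(nrow(extra)))
  grown <- patient_dataset(rbind(ds$records, extra))
  expect_true(estimate_a1c(grown)$available)
})

test_that("eA1c is hidden by default and shown on request", {
  ds <- make_bg_dataset(7, 3)
  expect_true(estimate_a1c(ds)$hidden)
  cfg <- default_config(); cfg$metrics$show_ea1c <- TRUE
  shown <- estimate_a1c(ds, cfg)
  expect_false(shown$hidden)
  expect_equal(shown$ngsp_pct, estimate_a1c(ds)$ngsp_pct)
})

test_that("NGSP to IFCC follows the master equation and is increasing", {
  expect_equal(ngsp_to_ifcc(6.5), 47.545, tolerance = 1e-9)
  expect_lt(abs(ngsp_to_ifcc(6.5) - 47.5), 0.1)
  expect_equal(ngsp_to_ifcc(23.50 / 10.93), 0, tolerance = 1e-12)
  x <- seq(4, 14, by = 0.1)
  expect_true(all(diff(ngsp_to_ifcc(x)) > 0))
})

test_that("the 100/85 and 400 rules divide the configured constants by TDD", {
  t0 <- as.POSIXct("2024-03-04 08:00:00", tz = "UTC")
  rows <- list()
  for (d in 0:1) {
    rows[[length(rows) + 1]] <- observation_record(
      paste0("ba", d), t0 + d * 86400, "insulin_basal", 20, source = "pen")
    rows[[length(rows) + 1]] <- observation_record(
      paste0("bo", d), t0 + d * 86400 + 3600, "insulin_bolus", 30,
      source = "pen")
  }
  ds <- patient_dataset(do.call(rbind, rows))
  r <- derived_ratios(ds)                       # TDD = 50 U/day
  expect_equal(r$tdd, 50)
  expect_equal(r$icr, 8.0)
  expect_equal(r$insulin_sensitivity, 2.0)
  expect_equal(r$basal_bolus_ratio, 40 / 60)
  cfg <- default_config(); cfg$metrics$isf_k <- 85
  expect_equal(derived_ratios(ds, cfg)$insulin_sensitivity, 85 / 50)
})

test_that("insulin ratios are absent without insulin data", {
  r <- derived_ratios(make_bg_dataset(2, 3))
  expect_true(is.na(r$tdd) && is.na(r$icr) && is.na(r$insulin_sensitivity))
})

test_that("time in range partitions on a closed target interval", {
  s <- time_in_range(c(3.2, 5.0, 9.9, 12.1), c(4, 10))
  expect_equal(unname(s$counts), c(1, 2, 1))
  expect_equal(unname(s$percents), c(25, 50, 25))
  # boundary values belong to the in-range bucket
  s <- time_in_range(c(4, 10), c(4, 10))
  expect_equal(s$counts[["in_range"]], 2)
  # empty input: zero counts, absent percents
  s <- time_in_range(numeric(), c(4, 10))
  expect_equal(sum(s$counts), 0)
  expect_true(all(is.na(s$percents)))
})

test_that("time-in-range percents always sum to 100 for nonempty data", {
  set.seed(11)
  for (i in 1:50) {
    v <- runif(sample(1:30, 1), 2, 16)
    expect_equal(sum(time_in_range(v, c(4, 10))$percents), 100,
                 tolerance = 1e-9)
  }
})

test_that("daily aggregation applies the per-type rule", {
  t0 <- as.POSIXct("2024-03-04 08:00:00", tz = "UTC")
  rows <- rbind(
    observation_record("i1", t0, "insulin_bolus", 2, source = "pen"),
    observation_record("i2", t0 + 3600, "insulin_bolus", 3, source = "pen"),
    observation_record("i3", t0 + 7200, "insulin_bolus", 4, source = "pen"),
    observation_record("g1", t0, "blood_glucose", 4),
    observation_record("g2", t0 + 3600, "blood_glucose", 8),
    observation_record("w1", t0, "weight", 81),
    observation_record("w2", t0 + 4 * 3600, "weight", 80),
    observation_record("m1", t0, "medication", 1),
    observation_record("m2", t0 + 3600, "medication", 1)
  )
  ds <- patient_dataset(rows)
  expect_equal(daily_aggregate(ds, "insulin_bolus")$value, 9)
  expect_equal(daily_aggregate(ds, "blood_glucose")$value, 6.0)
  expect_equal(daily_aggregate(ds, "weight")$value, 80)   # latest of day
  expect_equal(daily_aggregate(ds, "medication")$value, 2) # count
})

test_that("summed daily insulin conserves the record total", {
  ds <- generate_scenario(1, days = 6, seed = 3)
  for (tp in c("insulin_bolus", "insulin_basal", "carbohydrate")) {
    expect_equal(sum(daily_aggregate(ds, tp)$value),
                 sum(ds$records$value[ds$records$data_type == tp]))
  }
})

test_that("the summary table has one row per type with exact counts", {
  ds <- generate_scenario(1, days = 30, seed = 1)
  tab <- summary_table(ds)
  bg <- tab[tab$data_type == "blood_glucose", ]
  expect_equal(bg$n_total, 300L)
  expect_equal(bg$avg_per_day, 10.0)
  expect_equal(nrow(tab), length(unique(ds$records$data_type)))
  expect_equal(tab$n_total, as.integer(
    table(ds$records$data_type)[tab$data_type]), ignore_attr = TRUE)
})

test_that("blood pressure rows carry no pooled SD; empty data gives an empty table", {
  t0 <- as.POSIXct("2024-03-04 08:00:00", tz = "UTC")
  rows <- rbind(
    observation_record("b1", t0, "blood_pressure", 128, value2 = 84),
    observation_record("b2", t0 + 3600, "blood_pressure", 131, value2 = 86)
  )
  tab <- summary_table(patient_dataset(rows))
  expect_true(is.na(tab$average_deviation[tab$data_type == "blood_pressure"]))
  expect_equal(nrow(summary_table(patient_dataset())), 0L)
})
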