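# In-code fixtures: small datasets built record by record.

# a blood-glucose-only dataset: `per_day` readings on each of `days` days,
# values recycled from `values`, spaced hourly from 08:00
make_bg_dataset <- function(days, per_day, values = 7.0,
                            start = "2024-03-04", source = "finger_prick") {
  t0 <- as.POSIXct(paste(start, "08:00:00"), tz = "UTC")
  rows <- list()
  v <- rep_len(values, days * per_day)
  k <- 0L
  for (d in seq_len(days) - 1L) {
    for (i in seq_len(per_day) - 1L) {
      k <- k + 1L
      rows[[k]] <- observation_record(
        id = sprintf("bg-%03d", k), timestamp = t0 + d * 86400 + i * 3600,
        data_type = "blood_glucose", value = v[k], source = source
      )
    }
  }
  patient_dataset(do.call(rbind, rows))
}

# one record, terse
rec1 <- function(ts, type, value, value2 = NA_real_, source = "manual",
                 id = "r1") {
  observation_record(id = id, timestamp = as.POSIXct(ts, tz = "UTC"),
                     data_type = type, value = value, value2 = value2,
                     source = source)
}

event_kinds <- function(events) vapply(events, function(e) e$kind, character(1))
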