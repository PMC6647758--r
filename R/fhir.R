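# FHIR R4 JSON ingestion/serialization for self-collected diabetes data.
# Only the profile actually emitted by patient diary apps is modeled:
# Observation (valueQuantity or systolic/diastolic components), Goal with a
# detailRange target, and MedicationStatement.

.LOINC <- "http://loinc.org"
.SNOMED <- "http://snomed.info/sct"
.CUSTOM <- "urn:fullflow:code"
.SOURCE_SYSTEM <- "urn:fullflow:source"

# Default code map; config-overridable in spirit, but apps in the wild used
# exactly these. Unknown codes fall through to other:<code>.
.code_map <- data.frame(
  system = c(rep(.LOINC, 7), .SNOMED,
             rep(.CUSTOM, 5)),
  code = c("14743-9", "2339-0", "15074-8", "85354-9", "29463-7", "8867-4",
           "9052-2", "226077002",
           "insulin-bolus", "insulin-basal", "carbohydrate",
           "physical-activity", "medication"),
  data_type = c("blood_glucose", "blood_glucose", "blood_glucose",
                "blood_pressure", "weight", "heart_rate", "calories",
                "carbohydrate",
                "insulin_bolus", "insulin_basal", "carbohydrate",
                "physical_activity", "medication"),
  stringsAsFactors = FALSE
)

# Canonical code written back out per data type.
.write_codes <- list(
  blood_glucose     = list(system = .LOINC, code = "15074-8",
                           display = "Glucose [Moles/volume] in Blood"),
  blood_pressure    = list(system = .LOINC, code = "85354-9",
                           display = "Blood pressure panel"),
  weight            = list(system = .LOINC, code = "29463-7",
                           display = "Body weight"),
  heart_rate        = list(system = .LOINC, code = "8867-4",
                           display = "Heart rate"),
  calories          = list(system = .LOINC, code = "9052-2",
                           display = "Calorie intake total"),
  carbohydrate      = list(system = .CUSTOM, code = "carbohydrate",
                           display = "Carbohydrate intake"),
  insulin_bolus     = list(system = .CUSTOM, code = "insulin-bolus",
                           display = "Insulin bolus dose"),
  insulin_basal     = list(system = .CUSTOM, code = "insulin-basal",
                           display = "Insulin basal dose"),
  physical_activity = list(system = .CUSTOM, code = "physical-activity",
                           display = "Physical activity duration"),
  medication        = list(system = .CUSTOM, code = "medication",
                           display = "Medication intake")
)

# types entered by hand in a diary app when no method/device says otherwise
.manual_types <- c("weight", "carbohydrate", "calories", "physical_activity",
                   "medication", "blood_pressure")

#' Map a terminology code to a data type and source
#'
#' Total, deterministic lookup from a coding (system + code) plus an
#' optional method coding/text into the internal data type and collection
#' source. Codes outside the map land on `"other:<code>"` so that new data
#' types are retained rather than dropped.
#'
#' @param system coding system URI (LOINC, SNOMED CT, or app-specific).
#' @param code code string within the system.
#' @param method optional method/device text (e.g. "capillary", "CGM
#'   sensor") used to separate finger-prick from sensor glucose.
#' @return list with elements `data_type` and `source`.
#' @export
map_code <- function(system, code, method = NULL) {
  hit <- .code_map$data_type[.code_map$system == system &
                             .code_map$code == code]
  data_type <- if (length(hit) == 1L) hit else paste0("other:", code)
  source <- .infer_source(method, data_type)
  list(data_type = data_type, source = source)
}

.infer_source <- function(method, data_type) {
  if (!is.null(method) && length(method) == 1L && !is.na(method) &&
      nzchar(method)) {
    m <- tolower(method)
    if (m %in% .sources) return(m)
    if (grepl("capillary|finger", m)) return("finger_prick")
    if (grepl("sensor|cgm|continuous", m)) return("cgm")
    if (grepl("pump", m)) return("pump")
    if (grepl("pen", m)) return("pen")
    if (grepl("manual", m)) return("manual")
  }
  if (data_type %in% .manual_types) "manual" else "unknown"
}

#' Read a FHIR R4 JSON bundle into a patient dataset
#'
#' Accepts a Bundle (any type) or a bare JSON array of resources.
#' Observation resources become observation records, Goal resources become
#' personal goals and MedicationStatement resources become medication
#' records. Glucose reported in mg/dL is converted to mmol/L (factor
#' 18.016); other units are taken at face value. Observations carrying
#' neither a value nor components are skipped with a warning.
#'
#' @param path path to a JSON file, or a JSON string.
#' @param timezone report timezone defining the calendar day.
#' @return a [patient_dataset()].
#' @export
read_fhir_bundle <- function(path, timezone = "UTC") {
  txt <- if (length(path) == 1L && !grepl("\n", path, fixed = TRUE) &&
             !grepl("^\\s*[{\\[]", path) && file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else {
    paste(path, collapse = "\n")
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      stop("FHIR bundle parse error at byte offset ",
           .error_offset(txt), ": ", conditionMessage(e), call. = FALSE)
    }
  )
  resources <- if (!is.null(parsed$resourceType) &&
                   identical(parsed$resourceType, "Bundle")) {
    lapply(parsed$entry, function(e) e$resource)
  } else if (is.null(names(parsed))) {
    parsed                       # bare array of resources
  } else {
    list(parsed)                 # single resource
  }
  rows <- list()
  goals <- list()
  for (res in resources) {
    if (is.null(res$resourceType)) next
    switch(res$resourceType,
      Observation = {
        rec <- .obs_to_record(res)
        if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
      },
      MedicationStatement = {
        rows[[length(rows) + 1L]] <- .medstmt_to_record(res)
      },
      Goal = {
        goals[[length(goals) + 1L]] <- .goal_to_goal(res)
      }
    )
  }
  records <- if (length(rows)) do.call(rbind, rows) else .empty_records()
  patient_dataset(records, goals, timezone = timezone)
}

# byte offset of the first point where the JSON prefix stops validating
.error_offset <- function(txt) {
  n <- nchar(txt, type = "bytes")
  lo <- 1L
  # coarse scan is fine for diagnostics; cap work on very long inputs
  step <- max(1L, n %/% 256L)
  for (i in seq(1L, n, by = step)) {
    if (!.could_be_prefix(substr(txt, 1L, i))) return(i)
    lo <- i
  }
  n
}

.could_be_prefix <- function(prefix) {
  # a prefix of valid JSON fails only with a premature-EOF class of error
  v <- jsonlite::validate(prefix)
  if (isTRUE(v)) return(TRUE)
  grepl("premature EOF", attr(v, "err"), fixed = TRUE)
}

.obs_to_record <- function(res) {
  coding <- res$code$coding[[1]]
  method <- res$method$coding[[1]]$code
  if (is.null(method)) method <- res$method$text
  mapped <- map_code(coding$system %||% "", coding$code %||% "", method)
  ts <- res$effectiveDateTime %||% res$effectivePeriod$start
  if (is.null(ts)) return(NULL)
  value2 <- NA_real_
  comment <- res$note[[1]]$text %||% NA_character_
  if (!is.null(res$component) && length(res$component) >= 2L) {
    # systolic/diastolic pair
    comp_vals <- c(systolic = NA_real_, diastolic = NA_real_)
    unit <- "mm[Hg]"
    for (comp in res$component) {
      ccode <- comp$code$coding[[1]]$code %||% ""
      v <- comp$valueQuantity$value
      if (identical(ccode, "8480-6")) comp_vals["systolic"] <- v
      if (identical(ccode, "8462-4")) comp_vals["diastolic"] <- v
    }
    if (any(is.na(comp_vals))) {
      warning("Observation ", res$id %||% "?",
              ": incomplete blood pressure components; skipped")
      return(NULL)
    }
    value <- comp_vals[["systolic"]]
    value2 <- comp_vals[["diastolic"]]
  } else if (!is.null(res$valueQuantity)) {
    value <- res$valueQuantity$value
    unit <- res$valueQuantity$unit %||% res$valueQuantity$code %||%
      canonical_unit(mapped$data_type)
  } else {
    warning("Observation ", res$id %||% "?",
            " lacks both value and components; skipped")
    return(NULL)
  }
  ref_low <- res$referenceRange[[1]]$low$value %||% NA_real_
  ref_high <- res$referenceRange[[1]]$high$value %||% NA_real_
  # canonical-unit conversion (Norwegian convention: glucose in mmol/L)
  if (identical(mapped$data_type, "blood_glucose") &&
      !is.null(unit) && grepl("^mg/dl$", unit, ignore.case = TRUE)) {
    value <- value / 18.016
    if (!is.na(ref_low)) ref_low <- ref_low / 18.016
    if (!is.na(ref_high)) ref_high <- ref_high / 18.016
    unit <- "mmol/L"
  }
  observation_record(
    id = res$id %||% "", timestamp = .parse_instant(ts),
    data_type = mapped$data_type, value = value, value2 = value2,
    unit = unit, source = mapped$source, ref_low = ref_low,
    ref_high = ref_high, comment = comment
  )
}

.medstmt_to_record <- function(res) {
  ts <- res$effectiveDateTime %||% res$effectivePeriod$start
  observation_record(
    id = res$id %||% "", timestamp = .parse_instant(ts),
    data_type = "medication", value = 1, unit = "1", source = "manual",
    comment = res$note[[1]]$text %||% NA_character_
  )
}

.goal_to_goal <- function(res) {
  target <- res$target[[1]]
  if (!is.null(target$detailRange)) {
    measure <- target$measure$coding[[1]]
    metric <- map_code(measure$system %||% "", measure$code %||% "")$data_type
    personal_goal(
      description = res$description$text %||% "",
      measurable = TRUE, metric = metric,
      target = c(target$detailRange$low$value, target$detailRange$high$value)
    )
  } else {
    personal_goal(description = res$description$text %||% "")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_instant <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  pat <- "^(\\d{4}-\\d{2}-\\d{2})[T ](\\d{2}:\\d{2}:\\d{2}(?:\\.\\d+)?)(Z|[+-]\\d{2}:?\\d{2})?$"
  for (i in seq_along(x)) {
    m <- regmatches(x[i], regexec(pat, x[i]))[[1]]
    if (length(m) == 0L) {
      out[i] <- as.POSIXct(x[i], tz = "UTC")   # date-only fallback
      next
    }
    base <- as.POSIXct(paste(m[2], m[3]), format = "%Y-%m-%d %H:%M:%OS",
                       tz = "UTC")
    off <- m[4]
    if (!is.na(off) && nzchar(off) && off != "Z") {
      sgn <- if (substr(off, 1, 1) == "+") 1 else -1
      hh <- as.numeric(substr(off, 2, 3))
      mm <- as.numeric(substr(off, nchar(off) - 1, nchar(off)))
      base <- base - sgn * (hh * 3600 + mm * 60)
    }
    out[i] <- base
  }
  out
}

.format_instant <- function(ts) {
  format(ts, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Serialize a patient dataset to a FHIR R4 JSON bundle
#'
#' Inverse of [read_fhir_bundle()] on all modeled fields: reading the
#' written bundle reproduces the dataset (record identity up to row order
#' stability, which the reader restores).
#'
#' @param dataset a [patient_dataset()].
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
write_fhir_bundle <- function(dataset, path = NULL) {
  entries <- lapply(seq_len(nrow(dataset$records)), function(i) {
    list(resource = .record_to_resource(dataset$records[i, ]))
  })
  goal_entries <- lapply(dataset$goals, function(g) {
    list(resource = .goal_to_resource(g))
  })
  bundle <- list(
    resourceType = "Bundle", type = "collection",
    entry = c(entries, goal_entries)
  )
  json <- jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

.record_to_resource <- function(rec) {
  if (rec$data_type == "medication") {
    res <- list(
      resourceType = "MedicationStatement", id = rec$id, status = "recorded",
      medicationCodeableConcept = list(text = "medication"),
      effectiveDateTime = .format_instant(rec$timestamp)
    )
    if (!is.na(rec$comment)) res$note <- list(list(text = rec$comment))
    return(res)
  }
  wc <- if (startsWith(rec$data_type, "other:")) {
    list(system = "urn:fullflow:other",
         code = sub("^other:", "", rec$data_type), display = "Unregistered")
  } else {
    .write_codes[[rec$data_type]]
  }
  res <- list(
    resourceType = "Observation", id = rec$id, status = "final",
    code = list(coding = list(wc)),
    effectiveDateTime = .format_instant(rec$timestamp)
  )
  if (!rec$source %in% "unknown") {
    res$method <- list(coding = list(list(system = .SOURCE_SYSTEM,
                                          code = rec$source)))
  }
  if (rec$data_type == "blood_pressure") {
    res$component <- list(
      list(code = list(coding = list(list(system = .LOINC, code = "8480-6"))),
           valueQuantity = list(value = rec$value, unit = "mm[Hg]")),
      list(code = list(coding = list(list(system = .LOINC, code = "8462-4"))),
           valueQuantity = list(value = rec$value2, unit = "mm[Hg]"))
    )
  } else {
    res$valueQuantity <- list(value = rec$value, unit = rec$unit)
  }
  if (!is.na(rec$ref_low) && !is.na(rec$ref_high)) {
    res$referenceRange <- list(list(low = list(value = rec$ref_low),
                                    high = list(value = rec$ref_high)))
  }
  if (!is.na(rec$comment)) res$note <- list(list(text = rec$comment))
  res
}

.goal_to_resource <- function(goal) {
  res <- list(
    resourceType = "Goal", lifecycleStatus = "active",
    description = list(text = goal$description)
  )
  if (goal$measurable) {
    wc <- .write_codes[[goal$metric]]
    res$target <- list(list(
      measure = list(coding = list(wc)),
      detailRange = list(low = list(value = goal$target[1]),
                         high = list(value = goal$target[2]))
    ))
  }
  res
}
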