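# FHIR bundle reading/writing and code mapping

glucose_obs_json <- '{
  "resourceType": "Bundle", "type": "collection",
  "entry": [{"resource": {
    "resourceType": "Observation", "id": "obs-1", "status": "final",
    "code": {"coding": [{"system": "http://loinc.org", "code": "15074-8"}]},
    "method": {"text": "capillary blood test"},
    "effectiveDateTime": "2024-03-04T08:15:00Z",
    "valueQuantity": {"value": 5.5, "unit": "mmol/L"},
    "referenceRange": [{"low": {"value": 4}, "high": {"value": 10}}]
  }}]
}'

test_that("a glucose Observation maps field by field", {
  ds <- read_fhir_bundle(glucose_obs_json)
  expect_equal(nrow(ds$records), 1L)
  r <- ds$records[1, ]
  expect_equal(r$id, "obs-1")
  expect_equal(r$data_type, "blood_glucose")
  expect_equal(r$value, 5.5)
  expect_equal(r$unit, "mmol/L")
  expect_equal(r$source, "finger_prick")
  expect_equal(r$ref_low, 4)
  expect_equal(r$ref_high, 10)
  expect_equal(r$timestamp, as.POSIXct("2024-03-04 08:15:00", tz = "UTC"))
  expect_equal(ds$period[["start"]], r$timestamp)
})

test_that("a two-component blood pressure Observation becomes one paired record", {
  json <- '{"resourceType":"Observation","id":"bp-1","status":"final",
    "code":{"coding":[{"system":"http://loinc.org","code":"85354-9"}]},
    "effectiveDateTime":"2024-03-04T10:00:00Z",
    "component":[
      {"code":{"coding":[{"system":"http://loinc.org","code":"8480-6"}]},
       "valueQuantity":{"value":132,"unit":"mm[Hg]"}},
      {"code":{"coding":[{"system":"http://loinc.org","code":"8462-4"}]},
       "valueQuantity":{"value":85,"unit":"mm[Hg]"}}]}'
  ds <- read_fhir_bundle(json)
  expect_equal(nrow(ds$records), 1L)
  expect_equal(ds$records$data_type, "blood_pressure")
  expect_equal(ds$records$value, 132)
  expect_equal(ds$records$value2, 85)
})

test_that("empty bundle gives an empty dataset with no period", {
  ds <- read_fhir_bundle('{"resourceType":"Bundle","type":"collection","entry":[]}')
  expect_equal(nrow(ds$records), 0L)
  expect_null(ds$period)
  expect_output(print(ds), "no data")
})

test_that("glucose in mg/dL is converted to mmol/L on ingest", {
  json <- '{"resourceType":"Observation","id":"x","status":"final",
    "code":{"coding":[{"system":"http://loinc.org","code":"2339-0"}]},
    "effectiveDateTime":"2024-03-04T08:00:00Z",
    "valueQuantity":{"value":99,"unit":"mg/dL"}}'
  ds <- read_fhir_bundle(json)
  expect_equal(ds$records$value, 99 / 18.016, tolerance = 1e-12)
  expect_equal(ds$records$unit, "mmol/L")
})

test_that("an Observation without value or components is skipped with a warning", {
  json <- '{"resourceType":"Bundle","type":"collection","entry":[
    {"resource":{"resourceType":"Observation","id":"no-val","status":"final",
     "code":{"coding":[{"system":"http://loinc.org","code":"15074-8"}]},
     "effectiveDateTime":"2024-03-04T08:00:00Z"}}]}'
  expect_warning(ds <- read_fhir_bundle(json), "skipped")
  expect_equal(nrow(ds$records), 0L)
})

test_that("malformed JSON raises a parse error naming a byte offset", {
  expect_error(read_fhir_bundle('{"resourceType": "Bundle", "entry": [}'),
               "parse error at byte offset")
})

test_that("map_code is total, deterministic and infers sources", {
  m <- map_code("http://loinc.org", "14743-9", method = "capillary")
  expect_equal(m$data_type, "blood_glucose")
  expect_equal(m$source, "finger_prick")
  m <- map_code("http://loinc.org", "15074-8", method = "CGM sensor")
  expect_equal(m$source, "cgm")
  m <- map_code("http://loinc.org", "XXXX")
  expect_equal(m$data_type, "other:XXXX")
  expect_equal(m$source, "unknown")
  m <- map_code("http://loinc.org", "29463-7")
  expect_equal(m$data_type, "weight")
  expect_equal(m$source, "manual")
  # determinism
  expect_identical(map_code("http://loinc.org", "8867-4"),
                   map_code("http://loinc.org", "8867-4"))
})

test_that("unrecognized coded Observations are retained as other(code)", {
  json <- '{"resourceType":"Observation","id":"k","status":"final",
    "code":{"coding":[{"system":"http://loinc.org","code":"2345-7"}]},
    "effectiveDateTime":"2024-03-04T08:00:00Z",
    "valueQuantity":{"value":1.8,"unit":"mmol/L"}}'
  ds <- read_fhir_bundle(json)
  expect_equal(ds$records$data_type, "other:2345-7")
  expect_equal(ds$records$unit, "mmol/L")
})

test_that("write/read round trip is the identity on all modeled fields", {
  for (sc in 1:3) {
    ds <- generate_scenario(sc, days = 3, seed = 11)
    back <- read_fhir_bundle(as.character(write_fhir_bundle(ds)))
    expect_equal(back$records, ds$records, ignore_attr = TRUE)
    expect_equal(back$period, ds$period)
    expect_equal(length(back$goals), length(ds$goals))
    for (i in seq_along(ds$goals)) {
      expect_equal(back$goals[[i]]$description, ds$goals[[i]]$description)
      expect_equal(back$goals[[i]]$measurable, ds$goals[[i]]$measurable)
      expect_equal(back$goals[[i]]$target, ds$goals[[i]]$target)
    }
  }
})

test_that("comments survive the round trip in Observation.note", {
  ds <- patient_dataset(rec1("2024-03-04 12:00:00", "carbohydrate", 45))
  ds$records$comment <- "pasta lunch"
  back <- read_fhir_bundle(as.character(write_fhir_bundle(ds)))
  expect_equal(back$records$comment, "pasta lunch")
})

test_that("records are time-ordered after reading, stable on ties", {
  recs <- rbind(
    rec1("2024-03-04 12:00:00", "carbohydrate", 45, id = "a"),
    rec1("2024-03-04 08:00:00", "blood_glucose", 6.1, id = "b"),
    rec1("2024-03-04 08:00:00", "insulin_bolus", 4, id = "c")
  )
  ds <- patient_dataset(recs)
  expect_equal(ds$records$id, c("b", "c", "a"))
  back <- read_fhir_bundle(as.character(write_fhir_bundle(ds)))
  expect_true(!is.unsorted(back$records$timestamp))
  expect_equal(back$records$id, c("b", "c", "a"))
})

test_that("empty dataset writes a bundle with zero entries", {
  j <- jsonlite::fromJSON(as.character(write_fhir_bundle(patient_dataset())),
                          simplifyVector = FALSE)
  expect_equal(j$resourceType, "Bundle")
  expect_equal(length(j$entry), 0L)
})
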