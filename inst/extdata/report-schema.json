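{
  "title": "fullflow report document",
  "description": "Structural contract for the serialized report. The in-package validate_report() enforces the same keys.",
  "schema_version": "1.0",
  "required": ["meta", "overview", "combined", "daily_distribution",
               "daily_evolution", "time_period", "data_list"],
  "meta": {
    "required": ["schema_version", "generated_at", "config_hash",
                 "timezone", "period"]
  },
  "overview": {
    "required": ["reliability", "data_summary", "ratios", "ea1c",
                 "bg_summary", "range_summary", "daily_averages",
                 "latest_values", "grades", "goals", "noticeable_events",
                 "event_distribution"]
  },
  "grades": {
    "enum": ["green", "orange", "red", "white"]
  },
  "event_kinds": {
    "enum": ["nocturnal_hypoglycemia", "hypoglycemia", "hyperglycemia",
             "high_blood_pressure", "missed_medication"]
  }
}
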