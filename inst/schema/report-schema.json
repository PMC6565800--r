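{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "muscleBIA pipeline report",
  "type": "object",
  "required": ["recordings", "zscores", "errors", "n_input", "n_fitted",
               "significance_threshold"],
  "properties": {
    "recordings": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["recording_id", "subject_id", "gender", "muscle", "side",
                     "z", "r", "xc", "pa", "fc", "re", "ri", "mc",
                     "rmse", "arc_coverage", "qc_accept"]
      }
    },
    "zscores": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["recording_id", "parameter", "value", "ref_mean",
                     "ref_sd", "z", "outlier"]
      }
    },
    "contrasts": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["parameter", "muscle", "context", "group_a", "group_b",
                     "n_a", "n_b", "test_used", "statistic", "p_value",
                     "percent_change", "significant"],
        "properties": {
          "p_value": {"type": "number", "minimum": 0, "maximum": 1},
          "test_used": {"enum": ["t_test", "mann_whitney"]}
        }
      }
    },
    "errors": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["recording_id", "spectrum_file", "error"]
      }
    },
    "n_input": {"type": "integer", "minimum": 0},
    "n_fitted": {"type": "integer", "minimum": 0},
    "significance_threshold": {"type": "number",
                               "exclusiveMinimum": 0, "exclusiveMaximum": 1}
  }
}
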