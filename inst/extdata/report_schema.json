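{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cimqc quality report",
  "type": "object",
  "required": ["toolkit_version", "ruleset_digest", "index_summary", "metrics", "stages_run"],
  "properties": {
    "toolkit_version": {"type": "string"},
    "ruleset_digest": {"type": "string"},
    "root": {"type": "string"},
    "stages_run": {"type": "array", "items": {"type": "string"}},
    "index_summary": {
      "type": "object",
      "required": ["providers", "patients", "series", "instances"],
      "properties": {
        "providers": {"type": "integer", "minimum": 0},
        "patients": {"type": "integer", "minimum": 0},
        "series": {"type": "integer", "minimum": 0},
        "instances": {"type": "integer", "minimum": 0},
        "masks": {"type": "integer", "minimum": 0},
        "skipped_files": {"type": "integer", "minimum": 0}
      }
    },
    "metrics": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["dimension", "numerator", "denominator"],
        "properties": {
          "dimension": {"type": "string"},
          "numerator": {"type": "integer", "minimum": 0},
          "denominator": {"type": "integer", "minimum": 0},
          "percentage": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
          "n_failing": {"type": "integer", "minimum": 0}
        }
      }
    },
    "fairness": {"type": ["object", "null"]},
    "dedup": {"type": ["object", "null"]},
    "annotation": {"type": ["object", "null"]},
    "profiles": {"type": ["array", "null"]},
    "deid": {"type": ["object", "null"]},
    "not_run": {"type": "array", "items": {"type": "string"}},
    "run_log": {"type": "array", "items": {"type": "string"}}
  }
}
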