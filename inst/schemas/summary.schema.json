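{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "gaitseg-summary",
  "description": "The six gait report indices, each as mean and standard deviation.",
  "type": "object",
  "required": ["format", "version", "cop_mean_velocity_cm_s",
               "mean_double_support_time_s", "mean_cadence_steps_min",
               "pct_stance", "pct_swing", "pct_double_support"],
  "properties": {
    "format": {"const": "gaitseg-summary"},
    "version": {"type": "string"},
    "cop_mean_velocity_cm_s": {"$ref": "#/definitions/index"},
    "mean_double_support_time_s": {"$ref": "#/definitions/index"},
    "mean_cadence_steps_min": {"$ref": "#/definitions/index"},
    "pct_stance": {"$ref": "#/definitions/index"},
    "pct_swing": {"$ref": "#/definitions/index"},
    "pct_double_support": {"$ref": "#/definitions/index"},
    "n_cycles": {"type": "integer", "minimum": 0}
  },
  "definitions": {
    "index": {
      "type": "object",
      "required": ["mean", "sd"],
      "properties": {
        "mean": {"type": ["number", "null"]},
        "sd": {"type": ["number", "null"], "minimum": 0}
      }
    }
  }
}
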