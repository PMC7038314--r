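{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "gaitseg-config",
  "description": "Analysis configuration; every field is optional and defaults to the package default.",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "detector": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "window": {"type": "number", "exclusiveMinimum": 0,
                   "description": "rolling-extrema window, s (default 1.5)"},
        "refractory": {"type": "number", "minimum": 0,
                       "description": "min gap between same-type events, s (default 0.3)"},
        "min_amplitude": {"type": "number", "minimum": 0,
                          "description": "min rolling range to arm detection, kPa (default 20)"}
      }
    },
    "contact_floor": {"type": "number", "minimum": 0,
                      "description": "total-pressure floor for CoP validity, kPa (default 10)"},
    "foot_length": {"type": "number", "exclusiveMinimum": 0,
                    "description": "foot length, mm (default 260)"},
    "zone_fractions": {
      "type": "array", "minItems": 3, "maxItems": 3,
      "items": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
      "description": "anteroposterior zone cuts as fractions of foot length (default 0.25, 0.45, 0.70)"
    },
    "full_window": {"type": "boolean",
                    "description": "use the full recording as the cadence window (default false)"}
  }
}
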