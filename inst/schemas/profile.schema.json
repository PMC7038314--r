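{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "gaitseg-profile",
  "type": "object",
  "required": ["format", "version"],
  "properties": {
    "format": {"const": "gaitseg-profile"},
    "version": {"type": "string"},
    "cycle_duration": {"type": "number", "exclusiveMinimum": 0},
    "stance_fraction": {"type": "number", "exclusiveMinimum": 0,
                        "exclusiveMaximum": 1},
    "subphase_fractions": {
      "type": "object",
      "required": ["ICP", "FFCP", "FFP", "FFPOP"],
      "additionalProperties": {"type": "number", "exclusiveMinimum": 0},
      "description": "fractions of stance, summing to 1"
    },
    "waveforms": {
      "type": "object",
      "description": "column-wise per-sensor activation table: site, start, end, attack, release (fractions of stance), peak (kPa, 0-1200)"
    },
    "phase_offset": {"type": "number", "minimum": 0, "exclusiveMaximum": 1},
    "noise_sigma": {"type": "number", "minimum": 0},
    "n_cycles": {"type": "integer", "minimum": 1},
    "fs": {"type": "number", "exclusiveMinimum": 0},
    "lead_in": {"type": "number", "minimum": 0},
    "tail": {"type": "number", "minimum": 0},
    "seed": {"type": "integer"}
  }
}
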