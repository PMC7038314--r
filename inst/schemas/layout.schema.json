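{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "gaitseg-layout",
  "type": "object",
  "required": ["format", "version", "feet"],
  "properties": {
    "format": {"const": "gaitseg-layout"},
    "version": {"type": "string"},
    "feet": {
      "type": "object",
      "required": ["left", "right"],
      "additionalProperties": {
        "type": "object",
        "required": ["foot_length_mm", "sensors"],
        "properties": {
          "foot_length_mm": {"type": "number", "exclusiveMinimum": 0},
          "sensors": {
            "type": "array",
            "minItems": 8,
            "maxItems": 8,
            "items": {
              "type": "object",
              "required": ["site", "x_ml_mm", "y_ap_mm"],
              "properties": {
                "site": {"enum": ["heel", "midfoot_lateral", "met1", "met3",
                                  "met5", "hallux", "toe2", "toe5"]},
                "x_ml_mm": {"type": "number"},
                "y_ap_mm": {"type": "number", "minimum": 0}
              }
            }
          }
        }
      }
    }
  }
}
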