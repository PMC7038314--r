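{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "gaitseg-annotation",
  "type": "object",
  "required": ["format", "version", "foot_side", "stances"],
  "properties": {
    "format": {"const": "gaitseg-annotation"},
    "version": {"type": "string"},
    "foot_side": {"enum": ["left", "right"]},
    "stances": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["stance_id", "subphase", "start_s", "end_s"],
        "properties": {
          "stance_id": {"type": "integer", "minimum": 1},
          "subphase": {"enum": ["ICP", "FFCP", "FFP", "FFPOP"]},
          "start_s": {"type": "number"},
          "end_s": {"type": "number"}
        }
      }
    },
    "skipped_stances": {"type": "array", "items": {"type": "integer"}}
  }
}
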