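{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "gaitseg-events",
  "type": "object",
  "required": ["format", "version", "foot_side", "initial_contacts_s",
               "toe_offs_s"],
  "properties": {
    "format": {"const": "gaitseg-events"},
    "version": {"type": "string"},
    "foot_side": {"enum": ["left", "right"]},
    "initial_contacts_s": {"type": "array",
                           "items": {"type": "number"},
                           "description": "strictly increasing, seconds"},
    "toe_offs_s": {"type": "array",
                   "items": {"type": "number"},
                   "description": "strictly increasing, seconds"}
  }
}
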