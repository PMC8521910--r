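{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Typing session record",
  "description": "One JSON object per line of a sessions.jsonl file. Timestamps are integer milliseconds since epoch; press and release are paired index-wise, sorted by ascending press time, with release[i] >= press[i]. No character content is ever stored.",
  "type": "object",
  "required": ["session_id", "subject_id", "press", "release"],
  "properties": {
    "session_id": { "type": "string", "minLength": 1 },
    "subject_id": { "type": "string", "minLength": 1 },
    "press": {
      "type": "array",
      "items": { "type": "integer" },
      "minItems": 1
    },
    "release": {
      "type": "array",
      "items": { "type": "integer" },
      "minItems": 1
    }
  },
  "additionalProperties": false
}
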