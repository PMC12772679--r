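{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "autofif-feedback-v1",
  "title": "Structured plan feedback",
  "type": "object",
  "properties": {
    "target_coverage": { "enum": ["good", "bad", "unchanged"] },
    "oar_dose": { "enum": ["good", "high", "unchanged"] },
    "oar_roles": {
      "type": "array",
      "items": { "enum": ["EYE_L", "EYE_R", "LENS_L", "LENS_R"] }
    }
  },
  "required": ["target_coverage", "oar_dose"]
}
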