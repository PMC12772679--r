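{
  "BRAIN_CTV": "^(brain|ctv)(?!.*stem)[_ -]*(ctv)?$",
  "EYE_L": "^(eye|globe)[_ -]*(l|lt|left)$|^l(t|eft)?[_ -]*(eye|globe)$",
  "EYE_R": "^(eye|globe)[_ -]*(r|rt|right)$|^r(t|ight)?[_ -]*(eye|globe)$",
  "LENS_L": "^lens[_ -]*(l|lt|left)$|^l(t|eft)?[_ -]*lens$",
  "LENS_R": "^lens[_ -]*(r|rt|right)$|^r(t|ight)?[_ -]*lens$"
}
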