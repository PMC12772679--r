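[
  {
    "input": "The target coverage is poor.",
    "output": { "target_coverage": "bad", "oar_dose": "unchanged", "oar_roles": [] }
  },
  {
    "input": "Coverage looks fine but the dose to both lenses is too high.",
    "output": { "target_coverage": "good", "oar_dose": "high", "oar_roles": ["LENS_L", "LENS_R"] }
  },
  {
    "input": "Please lower the mean dose to the right eye.",
    "output": { "target_coverage": "unchanged", "oar_dose": "high", "oar_roles": ["EYE_R"] }
  },
  {
    "input": "Looks good overall, nothing to change.",
    "output": { "target_coverage": "good", "oar_dose": "good", "oar_roles": [] }
  }
]
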