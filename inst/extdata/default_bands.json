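[
  {"name": "nucleic_acids",  "center": 788,  "width": 8,  "shape": "lorentzian", "halfwidth": 10},
  {"name": "glycogen",       "center": 850,  "width": 10, "shape": "lorentzian", "halfwidth": 10},
  {"name": "polysaccharide", "center": 940,  "width": 10, "shape": "lorentzian", "halfwidth": 10},
  {"name": "phenylalanine",  "center": 1004, "width": 6,  "shape": "lorentzian", "halfwidth": 10},
  {"name": "amide_III",      "center": 1350, "width": 14, "shape": "lorentzian", "halfwidth": 10},
  {"name": "lipid_CH2",      "center": 1440, "width": 12, "shape": "lorentzian", "halfwidth": 10},
  {"name": "amide_I",        "center": 1650, "width": 14, "shape": "lorentzian", "halfwidth": 10}
]
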