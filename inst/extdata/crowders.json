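[
  {"name": "dextrose", "molar_mass": 180.16, "class": "monomer", "Rh": 4.2},
  {"name": "sucrose", "molar_mass": 342.30, "class": "monomer", "Rh": 5.2},
  {"name": "ethylene glycol", "molar_mass": 62.07, "class": "monomer"},
  {"name": "1-ethyl-2-pyrrolidone", "molar_mass": 113.16, "class": "monomer"},
  {"name": "dextran 40", "molar_mass": 40000, "class": "polymer", "Rh": 4.78},
  {"name": "ficoll 70", "molar_mass": 70000, "class": "polymer", "Rh": 40},
  {"name": "PEG 8", "molar_mass": 8000, "class": "polymer", "Rh": 27.5},
  {"name": "PVP 40", "molar_mass": 40000, "class": "polymer", "Rh": 5.10}
]
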