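{
  "nitinol": {
    "name": "Nitinol archwire",
    "density_kg_m3": 6450,
    "youngs_modulus_Pa": 8.3e7,
    "shear_modulus_Pa": 3.12e7,
    "poisson": 0.33
  },
  "nicr": {
    "name": "Ni-Cr alloy (brackets and tubes)",
    "density_kg_m3": 8500,
    "youngs_modulus_Pa": 2.1e11,
    "shear_modulus_Pa": 8.015e10,
    "poisson": 0.31
  },
  "bone": {
    "name": "Bone (maxilla, mandible)",
    "density_kg_m3": 1400,
    "youngs_modulus_Pa": 1.0e10,
    "shear_modulus_Pa": 3.84e9,
    "poisson": 0.31
  },
  "enamel": {
    "name": "Tooth enamel",
    "density_kg_m3": 2958,
    "youngs_modulus_Pa": 7.79e10,
    "shear_modulus_Pa": 2.996e10,
    "poisson": 0.3
  }
}
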