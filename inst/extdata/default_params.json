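{
  "pollen": {
    "mu": 5,
    "n_star": 66100,
    "t_b": 13,
    "t_c": 48,
    "t_opt": 18,
    "t_0": 1
  },
  "viability": {
    "alpha_max": 0.94,
    "theta1": 0.78,
    "theta2": -0.11,
    "t_opt": 18
  },
  "germination": {
    "alpha_max": 0.31,
    "theta1": 0.34,
    "theta2": -0.06,
    "t_opt": 18
  },
  "seed_link": {
    "slope": 0.0016,
    "intercept": 2.23
  },
  "mass_link": {
    "slope": 0.078,
    "intercept": 2.06
  },
  "conversion": {
    "c_flower_to_fruit": 1,
    "vol_chamber": 0.2,
    "vol_sample": 200
  },
  "fruit_set": null,
  "mass_unit": "g"
}
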