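{
  "note": "Synthetic example fruit-set quadratic: no published coefficients exist, so these were chosen to pass through plausible point values (0.70 at 14 C, 0.90 at 30 C).",
  "fruit_set": {
    "c0": -0.35,
    "c1": 0.1041667,
    "c2": -0.0020833
  }
}
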