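{
  "p_kPa": [0, 0.4, 5],
  "ratio": [1, 0.997287266698696, 0.974287266698696],
  "note": "Niatel-type humid/dry W ratio, piecewise linear; level calibrated to the adopted mean humidity correction."
}
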