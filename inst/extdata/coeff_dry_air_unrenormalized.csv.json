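{
  "material": "dry_air",
  "variant": "unrenormalized",
  "provenance": "Generated by tools/make_fixtures.R from standard XCOM-class anchor values; log-log interpolated to a 0.5 keV grid. Renormalized variant: photoelectric part scaled by 0.97."
}
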