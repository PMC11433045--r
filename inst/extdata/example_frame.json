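{
  "_comment": "synthetic example fitting parameters (not from any subject)",
  "ipd_mm": 62,
  "pupil_height_mm": 22,
  "bvd_mm": 12,
  "cre_to_lens_mm": 25.5,
  "pantoscopic_deg": 0,
  "wrap_deg": 0
}
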