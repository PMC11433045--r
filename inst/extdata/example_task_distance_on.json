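{
  "_comment": "on-axis distance-reading condition: screen 5.25 m away, 31.7 cm above primary gaze, 4.2 x 2.3 deg",
  "name": "distance_on",
  "target_distance_m": 5.25,
  "azimuth_offset_deg": 0,
  "target_height_m": 0.317,
  "angular_width_deg": 4.2,
  "angular_height_deg": 2.3,
  "mean_pupil_diameter_mm": 3.73
}
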