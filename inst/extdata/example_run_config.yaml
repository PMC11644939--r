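camera:
  focal_length_px: 2400
  baseline_mm: 75
  width_px: 320
  height_px: 320
  mount_height_mm: 1200
calibration:
  reference_point: [6, 6]
  window: 2
  sat_min_mm: 300
  sat_max_mm: 1500
  flatness_tolerance_mm: 10
detection_threshold: 0.5
segmentation:
  tol: 0.05
seed: 1
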