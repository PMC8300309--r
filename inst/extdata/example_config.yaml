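# circumnut run configuration (example)
frame_interval_s: 178.571429
smoothing_window: 5
min_prominence: 1.5707963
direction_tolerance: 1.2
raster_resolution_mm: 0.1
speed_unit: mm/h
stimulus:
  x: 40.0
  z: 0.0
  model: vertical-line
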