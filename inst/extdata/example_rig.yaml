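world_origin: simulated calibration target corner
left:
  fx: 1400.0
  fy: 1400.0
  cx: 960.0
  cy: 540.0
  skew: 0.0
  distortion:
    k1: -0.12
    k2: 0.03
    k3: 0.0
    p1: 0.0005
    p2: -0.0003
  rotation:
  - -0.9828722
  - 0.0
  - 0.1842885
  - 0.0
  - -1.0
  - 0.0
  - 0.1842885
  - 0.0
  - 0.9828722
  translation:
  - 1.687539e-14
  - 0.0e+00
  - 8.1394103e+02
  image_size:
  - 1920
  - 1080
right:
  fx: 1400.0
  fy: 1400.0
  cx: 960.0
  cy: 540.0
  skew: 0.0
  distortion:
    k1: -0.1
    k2: 0.02
    k3: 0.0
    p1: 0.0005
    p2: -0.0003
  rotation:
  - -0.9828722
  - -0.0
  - -0.1842885
  - 0.0
  - -1.0
  - 0.0
  - -0.1842885
  - 0.0
  - 0.9828722
  translation:
  - -1.687539e-14
  - 0.0e+00
  - 8.1394103e+02
  image_size:
  - 1920
  - 1080
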