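# Example polardrum run configuration.
# Lengths in cm, angles in degrees, resolutions in px.
arena:
  wall_width: 38.5
  wall_height: 30.0
  panel_px_w: 192
  panel_px_h: 148
  viewer_eye_height: 15.0
stimulus:
  spatial_freq: 0.05     # cycles per degree of azimuth
  contrast_level: 1.0
  channel: intensity
  speed: 6               # deg/s drum rotation
  direction: ccw
  duration: 5
  fps: 30
staircase:
  resolution: 0.01       # bisection stops below this bracket width
  sentinel: 1.2          # non-responder bookkeeping value
seed: 1
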