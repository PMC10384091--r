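# Measurement configuration for a top-view stereo RGB-D rig.
# The camera height above the water surface is derived as
# camera_placement_mm - water_depth_mm. Omit the whole `refraction`
# section to measure without refraction correction.
camera:
  fx: 600          # focal length, pixels
  fy: 600
  cx: 319.5        # principal point, 0-based pixels
  cy: 239.5
  baseline_mm: 50  # stereo baseline
  width: 640
  height: 480
refraction:
  n_air: 1.0
  n_water: 1.333
  camera_placement_mm: 750   # camera to container bottom
  water_depth_mm: 500
segmentation:
  gmm_components: 5
  gamma: 50
  n_iterations: 5
  stretch_low_pct: 1
  stretch_high_pct: 99
  brightness_offset: 0
  seed: 1
skeleton:
  max_deletions: null        # default: 15% of the skeleton pixel count
measurement:
  theta_threshold_deg: 5.0
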