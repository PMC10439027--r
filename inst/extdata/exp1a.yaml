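# Circular-field session: cued/uncued orientation discrimination at four
# retinal eccentricities on a full-height circular dynamic pink-noise field.
# Nominal ppd derived from the display geometry (field radius 14.32 deg
# spanning half the 768-px screen height).
schema_version: 1
display:
  width_px: 1024
  height_px: 768
  ppd: 26.8
  refresh_hz: 120
noise:
  update_rate: 60        # noise frames per second; each shown twice at 120 Hz
  n_steps: 4             # hybrid steps between keyframes
  mean_luminance: 0.5
  contrast: 0.2
  field_px: [768, 768]
  shape: circular
  field_radius_deg: 14.32
  field_ramp_deg: 2.39
signal:
  r_deg: 1.75
  w_deg: 0.875
  tilts_deg: [-40, 40]
  sigma_ladder_deg: [30, 35, 40, 45, 50, 55, 60, 65, 70]
placement:
  mode: eccentricity
  values_deg: [0, 3.5, 7, 10.5]
timing_ms:
  fixation_min: 400
  fixation_max: 800
  cue: 66.66666667       # 4 frames at 60 Hz (75 ms is not frame-aligned)
  cue_signal_delay: 100  # 6 frames
  signal: 50             # 3 frames
  mask: 500              # 30 frames
trials:
  n_trials: 180
  conditions: [cued, uncued]
seed: 1
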