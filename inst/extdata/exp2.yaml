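# Rectangular-strip session: brief orientation signals at nine horizontal
# positions on a 2.5 x 20 deg dynamic pink-noise strip with five circular
# placeholder frames. The pixel field is taller than the visible strip so
# the signal window's soft support fits; the rectangular aperture is
# applied at display/export time.
schema_version: 1
display:
  width_px: 1024
  height_px: 768
  ppd: 26.8
  refresh_hz: 120
noise:
  update_rate: 120
  n_steps: 4
  mean_luminance: 0.5
  contrast: 0.2
  field_px: [128, 544]
  shape: rectangular
  field_height_deg: 2.5
  field_width_deg: 20
signal:
  r_deg: 1.0
  w_deg: 0.875
  tilts_deg: [-40, 40]
  sigma_ladder_deg: [10, 20, 30, 40, 50]   # threshold-task ladder
placement:
  mode: position
  values_deg: [-8, -6, -4, -2, 0, 2, 4, 6, 8]
timing_ms:
  fixation_min: 300
  fixation_max: 1000
  cue: 0                   # no cue in the main task
  cue_signal_delay: 0
  signal: 41.66666667      # 5 frames at 120 Hz (~42 ms)
  mask: 500                # within the 300-650 ms masking range
trials:
  n_trials: 378
  conditions: [uncued]
seed: 1
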