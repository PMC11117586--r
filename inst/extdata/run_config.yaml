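# Example run configuration for the gazewin pipeline.
screen:
  width_px: 1920
  height_px: 1080
  diagonal_inches: 23        # or give physical_width_cm / physical_height_cm
  viewing_distance_cm: 57
fixation_params:
  tolerance_px: 40           # spatial dispersion threshold
  min_duration_ms: 80        # temporal threshold
  max_gap_ms: 100            # blink robustness
analysis:
  convention: mean_per_fixation   # or total_per_presentation
  alpha: 0.05
simulation:
  n_per_condition:
    NVR: 54
    PFFV: 59
    FV: 50
seed: 1
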