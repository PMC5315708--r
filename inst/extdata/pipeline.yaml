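# Example scopemetrics pipeline configuration.
# Values shown are the package defaults; any key may be omitted.
cohort:
  # exercises: defaults to the 25 standard simulator exercises
  seed: 42
  sample_rate: 50
  group_sizes:
    new: 18
    intermediate: 8
    experienced: 13
segmentation:
  speed_threshold: 0.002   # m/s
  min_episode: 0.10        # s
  merge_gap: 0.20          # s
  smoothing_window: 5      # samples, odd
  use_kinematics: false    # event markers take precedence by default
metrics:
  mwr_mode: scaled_max     # or: percentile
  cint_convention: gap     # or: start_to_start
validity:
  variant: student         # or: welch
  alpha: 0.05
  paired: true
output_dir: results
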