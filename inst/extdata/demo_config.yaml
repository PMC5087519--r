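# Demo configuration for run_pipeline(): small synthetic run of both
# imaging channels that completes in well under a minute.
n_per_class: 6
seed: 42
families:
- color
windows_seconds:
- 5.0
- 10.0
speckle:
  height: 32
  width: 32
  n_frames: 125
  grain_sigma: 1.0
  bit_depth: 256
  class_rhos:
  - 0.95
  - 0.5
classifier:
  gamma: 10.0
  sigma: 1.0
  train_fraction: 0.666666666666667
  n_repeats: 10
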