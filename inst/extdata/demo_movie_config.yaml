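# Demo run configuration: a 48-hour conversion movie starting from 110
# MEF-like cells, with scheduled with-/without-mitosis conversions to
# neuron-like and shrunken morphologies, plus the expression-compendium
# settings. Values mirror the package defaults; edit freely.
schema_version: "1.0"
seed: 20260101
movie:
  n_frames: 48
  field_size: [1500, 1500]
  n_initial_cells: 110
  archetype_mix: {MEF-like: 1.0, neuron-like: 0.0, shrunken: 0.0}
  motion_step_sd: {MEF-like: 3.0, neuron-like: 1.5, shrunken: 2.0}
  division_prob: {MEF-like: 0.015, neuron-like: 0.045, shrunken: 0.040}
  apoptosis_prob: 0.001
  conversion_schedule:
    - {fraction: 0.25, mode: with-mitosis, frame_lo: 12, frame_hi: 30, target: neuron-like}
    - {fraction: 0.25, mode: without-mitosis, frame_lo: 24, frame_hi: 44, target: neuron-like}
    - {fraction: 0.15, mode: without-mitosis, frame_lo: 20, frame_hi: 40, target: shrunken}
thresholds: {}
tracking: {}
kinetics: {persistence: 3, mitosis_threshold: 1, frames_per_day: 24, grid_k: 5}
compendium: {n_datasets: 30}
scoring: {up_threshold: 1.5, strong_quantile: 0.75}
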