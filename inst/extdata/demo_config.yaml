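# Demonstration run: three disease stages, five replicate phantoms each,
# quantified from the generator's ground-truth masks (set use_truth_masks to
# false to exercise the rules-based segmenter instead).
seed: 1
out_dir: fibromorph_run
log_level: info
phantom:
  shape: [96, 96, 96]
  voxel_size_um: 1.6
  stages:
    label: ["4wk", "6wk", "8wk"]
    lesion_target_fraction: [0.05, 0.20, 0.40]
  n_replicates: 5
segment:
  use_truth_masks: true
stats:
  alpha: 0.05
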