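# Example pipeline configuration (see run_config() / read_run_config()).
out_dir: results/example_run
seed: 1
stages: [generate, decode, ddm, pid]
sim:
  n_participants: 2
  n_trials_per_cell: 2
  conditions: [V, H, VH]
  amplitude_levels: [0.75, 1.25]
  fs: 40
  n_channels: 4
  trial_duration: 2
  coupling_snr: {V: 1, H: 1, VH: 2}
decode:
  lambda: 4
  folds: 2
ddm:
  spec:
    drift: ["1", "r2_s"]
    ndt: ["1"]
    boundary: ["1"]
  chains: 2
  n_samples: 500
  burn: 200
  thin: 5
pid:
  lambda: 4
  folds: 2
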