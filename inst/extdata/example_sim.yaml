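# Example generator configuration (see sim_config() / read_sim_config()).
n_participants: 2
n_trials_per_cell: 2
conditions: [V, H, VH]
amplitude_levels: [0.75, 1.25]
fs: 40
n_channels: 4
trial_duration: 2
coupling_snr: {V: 1, H: 1, VH: 2}
seed: 1
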