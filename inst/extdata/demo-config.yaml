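# Demo configuration: simulated study, 4 control vs 4 treated replicates.
seed: 1
simulate:
  n_per_group: 4
  dispersion: 0.05
  signal_sd: 0.25
thresholds:
  alpha: 0.05
  fc_cut: 2
  p_cut: 0.005
  min_replicates: 2
  n_perm: 2000
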