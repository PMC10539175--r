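# Example configuration for run_full_analysis().
seed: 7
simulate:
  "n": 619   # quoted: a bare `n` is YAML-1.1 boolean false
  scenario:
    kind: plateau
    d0: 3
    low_level: 0.5
    high_level: 1.5
dose_metrics: [per_bw, per_bv]
mcmc:
  n_draws: 1000
  burn: 400
  chains: 2
  grid_size: 200
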