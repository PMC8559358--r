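# Small end-to-end pipeline configuration: 3 simulated individuals on a
# 1200 km grid, short chains. See default_pipeline_config() for the full
# set of keys and their defaults.
truncated: false
simulate:
  n_individuals: 3
  n_fixes: 220
  nx: 30
  ny: 30
fit:
  n_chains: 3
  n_iter: 1000
  thin: 5
popfit:
  n_iter: 2000
  n_burnin: 500
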