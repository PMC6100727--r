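# Scaled-down demo configuration for run_pipeline() / the CLI wrapper.
# Any key omitted here falls back to default_config().
seed: 1
out_dir: thermoevolve_demo
fixtures:
  n_snps: 2000
  ne: 219
  generations: 59
  coverage: 80
  block_snps: 28
  block_p0: 0.44
  block_s: 0.07
scan:
  n_neutral_runs: 3
  top_k: 100
qt:
  background_counts: [10, 100, 1000]
  optima: [0.3, 0.5, 0.7]
  n_sims: 10
clinal:
  n_snps: 197
  n_candidates: 21
  n_draws: 10000
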