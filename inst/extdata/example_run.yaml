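# Example colonywatch run configuration.
# Exactly one of `simulate:` (fields of simulation_truth) or `inputs:`
# (paths to image_scores/sites/breeding CSVs) must be present.
simulate:
  n_sites_per_subcolony: [27, 52]
  n_seasons: 3
  image_interval: 15
presence_filters: [any, pair]
hypotheses: [assoc1, assoc2, "1", 2a, 2b]
mcmc:
  profile: fast        # canonical = 3 x 200,000 / burn-in 15,000 / thin 3
path_n_rows: 50
seed: 1
output_dir: colonywatch_run
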