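# Example study configuration.
# Keys mirror study_grid() arguments; coefficient and extension blocks are
# optional overrides.
scenarios: [1, 6]
K_values: [30, 40, 80]
n_reps: 200
models: ["1e", "1f", "2g", "2h", "2i", "2j"]
master_seed: 20231028
coefficients:
  beta0: 0.30
  beta_region: 0.0
extensions:
  urban_heterogeneity: false
  race_heterogeneity: false
  baseline_boosted_fraction: 0.0
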