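# Example pipeline configuration: synthetic 41-city x 6-year panel,
# contemporaneous CRS frontier, random-effects Tobit second stage.
synthetic:
  n_units: 41
  n_periods: 6
  seed: 1
model:
  rts: CRS
  frontier_scope: contemporaneous
  undesirable_mode: eq1
malmquist:
  bad_mode: as_input
  orientation: output
tobit:
  enabled: true
  model: random_effects
  quad_nodes: 12
  lower: 0
output_dir: medeff_out
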