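# Example simulation profile. Any key left out falls back to the
# package default; see ?bioenergetics_params, ?mortality_params,
# ?system_geometry and ?experiment_config for the full schema.
bioenergetics:
  q10_metabolism: 2.0
  q10_ingestion: 2.0
  assimilation_efficiency: 0.7
  breeding_season: [121, 212]
mortality:
  m_juvenile: 0.008
  gamma: 0.0001
geometry:
  area: 20
  n_patches: 500
  vegetated_ratio: 0.1
experiment:
  latitudes: [50, 55, 60]
  delta_ts: [0, 1.4, 2.7, 4.4]
  warmup_years: 10
  treatment_years: 10
  n_replicates: 15
  base_seed: 1
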