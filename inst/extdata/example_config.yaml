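# Example end-to-end configuration for run_pipeline(): a scaled-down
# synthetic study (two reference pools, 12 microsatellite loci, 40 tagged
# fish) that runs in a few seconds.
synthetic:
  fst: 0.02
  n_loci: 12
  alleles_per_locus: 15
  sample_sizes: [120, 120]
  n_tagged: 40
  philopatry_prob: 0.9
  track_noise_sd: 0.2
  outlier_rate: 0.05
permutation_reps: 199
exclusion_sims: 500
subsample_reps: 5
boschloo:
  sided: one
  grid_size: 1001
seed: 42
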