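# Demo pipeline config: simulate a 3 x 10-sample cohort and run every stage.
simulation:
  n_per_group: 10
  seed: 0
params:
  fold_min: 2
  q_max: 0.05
  fpkm_min: 100
  cutoff: 30
  reference_gene: ABL1
output_dir: leukdx_demo_output
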