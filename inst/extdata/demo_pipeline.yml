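# Demo pipeline: small synthetic dataset through every stage.
stages: [simulate, select, treeclean, concat, recode, saturation]
sim:
  n_taxa: 10
  n_genes: 20
selection: {}
long_branch: {}
occupancy: 0.5
recode_scheme: dayhoff6
seed: 42
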