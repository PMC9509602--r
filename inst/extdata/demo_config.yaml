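# Fully synthetic demo cohort: small enough to run end to end in well under
# a minute on one CPU, with one planted 5-fold stone-side effect.
seed: 99
simulate:
  n_phyla: 3
  n_genera: 6
  n_species: 15
  n_subjects: 6
  reads_per_sample: 2500
  effects:
    s0001: 5
parameters:
  folds: 4
  repeats: 2
  n_trees: 60
  n_perm: 49
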