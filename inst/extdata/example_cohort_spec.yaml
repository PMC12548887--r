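# Synthetic two-layer cohort specification (see ?read_cohort_spec).
n_subjects: 400
seed: 7
noise_sd: 1.0
group_fractions:
  control: 0.4
  MCI: 0.35
  AD: 0.25
missingness:
  molecular: 0.2
  phenotype: 0.05
layers:
  - name: molecular
    n_variables: 6
  - name: phenotype
    n_variables: 4
    kinds: [continuous, continuous, ordinal, categorical]
    n_levels: 3
blocks:
  - layer: molecular
    size: 3
    loading: 0.8
chains:
  - variables: [molecular_05, phenotype_01]
    strength: 0.7
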