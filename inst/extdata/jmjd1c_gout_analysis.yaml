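loci:
  - label: JMJD1C
    exposure: testosterone_jmjd1c.tsv
    mode: single_variant
outcomes:
  - label: Gout
    path: gout_jmjd1c_derived.tsv
methods:
  - ivw
  - weighted_median
  - egger
effects_model: fixed
delta_order: first
palindromic_policy: drop
n_boot: 1000
seed: 42
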