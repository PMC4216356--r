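# Example simulation configuration for `edemascore.R simulate`
seed: 7
cohort:
  n_edema: 10
  n_no_edema: 10
  n_borderline: 0
readers:
  n: 7
  rating_noise: 0.05
  standard_sens: 0.5714
  standard_spec: 0.90
severity:
  preset: paper_like
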