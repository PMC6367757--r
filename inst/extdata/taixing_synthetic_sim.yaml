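# Taixing-like synthetic cohort: 13,176 women, uniform entry ages 25-70,
# 7 years administrative follow-up, cohort marginal factor prevalences.
cohort_size: 13176
horizon: 7
entry_ages:
  min: 25
  max: 70
region: taixing_synthetic.yaml
prevalences:
  abortions: [9612, 3210, 320]
  age_first_birth: [9853, 3138, 151]
  benign_disease: [13096, 46]
  bmi: [9039, 3690, 413]
  family_history: [13052, 90]
  satisfaction: [6235, 6907]
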