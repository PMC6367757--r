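# Synthetic Taixing-like region: plausible county-registry rates, NOT official
# surveillance figures. The attributable risk 0.78 calibrates the baseline and
# applies to this region's rate tables only.
name: taixing_synthetic
incidence_table: taixing_synthetic_incidence.csv
mortality_table: taixing_synthetic_mortality.csv
attributable_risk: 0.78
risk_table: taixing_reference_risk_table.csv
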