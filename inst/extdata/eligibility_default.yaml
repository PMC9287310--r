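# Default external-cohort selection steps.  These mirror the attrition flow
# of a third-line refractory selection: treatment-line setting, required
# prior chemotherapy exposure, and biomarker-based exclusions.  The fields
# are the synthetic generator's eligibility columns; real cohorts supply
# their own rule file over their own columns.
- name: third_line_setting
  field: line_of_therapy
  op: eq
  value: 3
  rationale: historical control patients must have received the study drug as third-line treatment
- name: prior_fluoropyrimidine_oxaliplatin_irinotecan
  field: prior_chemo
  op: eq
  value: "yes"
  rationale: required exposure to 5FU, oxaliplatin and irinotecan in earlier lines
- name: no_braf_egfr_msih
  field: biomarker_excluded
  op: eq
  value: "no"
  rationale: BRAF-mutant, EGFR-treated and MSI-high patients are excluded by the current trial
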