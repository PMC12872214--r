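# Experiment configuration for the two-source linkage study.
# cohort: arguments understood by cohort_config(); rules: named
# deterministic field conjunctions; probabilistic: named criteria;
# ml: settings shared by both ML modes.

cohort:
  n_source_a: 2642
  seed: 20260930

rules:
  dob_msdate: [dob, ms_first_dx_date]
  dob_sex_nat: [dob, sex, nationality]
  dob_msdate_meds: [dob, ms_first_dx_date, medications]
  dob_msdate_adm: [dob, ms_first_dx_date, admissions]

probabilistic:
  dob_block:
    block: [dob]
    compare: [sex, nationality, coverage, facility, region, ms_first_dx_date]
    threshold: 0.0
    one_to_one: true
  msdate_block:
    block: [ms_first_dx_date]
    compare: [sex, nationality, coverage, facility, region, dob]
    threshold: 0.0
    one_to_one: true

ml:
  block: [dob]
  fields: [sex, nationality, coverage, facility, region, ms_first_dx_date,
           other_dx, medications, admissions]
  train_fraction: 0.75
  bootstrap: 100
  seed: 20260930
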