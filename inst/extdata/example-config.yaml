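# Example synthetic-cohort configuration (reduced sizes).
# Keys mirror the arguments of cohort_config(); matrices are lists of rows.
n_per_study:
  HRS: 400
  ELSA: 400
  H2000: 250
wave_years: [2000, 2002, 2004, 2006, 2008, 2010, 2012]
baseline_age_range: [50, 85]
latent:
  states: [good, limited, severe]
  init: [0.70, 0.24, 0.06]
  trans:
    - [0.86, 0.11, 0.03]
    - [0.18, 0.68, 0.14]
    - [0.03, 0.17, 0.80]
age_bands: [65, 76]
mortality_coefs:
  intercept: -4.8
  age: 0.09
  state: [0.0, 0.8, 1.8]
missingness:
  wave_nonresponse: 0.12
  item: 0.02
  structural:
    - study: ELSA
      years: [2000]
      vars: all
    - study: H2000
      years: [2002, 2004, 2006, 2008]
      vars: all
    - study: HRS
      years: all
      vars: [adl2]
    - study: H2000
      years: all
      vars: [iadl6]
baseline_wave:
  HRS: 2000
  ELSA: 2002
  H2000: 2000
single_followup:
  study: H2000
  years: [2010, 2012]
sex_p_male: 0.45
seed: 42
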