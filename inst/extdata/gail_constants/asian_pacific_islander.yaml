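# Gail-model constant block: Asian / Pacific Islander.
version: "1.0"
race_group: asian_pacific_islander
provenance: >
  Log relative-risk coefficients and attributable-risk adjustment transcribed
  from the Asian American Breast Cancer Study model as distributed with the
  NCI Breast Cancer Risk Assessment Tool. This release ships the SEER
  1983-1987 White composite incidence and competing-mortality table for all
  race groups; race-specific hazard tables are a planned extension (see the
  methods vignette, "Limitations").
beta:
  n_biopsies: 0.5526361226
  age_at_menarche: 0.0749925759
  age_at_first_birth: 0.2763826829
  n_relatives: 0.7918563372
  biopsies_x_age_ge50: 0.0
  first_birth_x_relatives: 0.0
hyperplasia_rr:
  present: 1.82
  absent_with_biopsy: 0.93
  unknown_or_no_biopsy: 1.00
one_minus_ar:
  age_lt50: 0.4751981
  age_ge50: 0.5031640
age_bands:
  - {start: 20, end: 25, lambda1: 0.0000100, lambda2: 0.0004930}
  - {start: 25, end: 30, lambda1: 0.0000760, lambda2: 0.0005310}
  - {start: 30, end: 35, lambda1: 0.0002660, lambda2: 0.0006250}
  - {start: 35, end: 40, lambda1: 0.0006610, lambda2: 0.0008250}
  - {start: 40, end: 45, lambda1: 0.0012650, lambda2: 0.0013070}
  - {start: 45, end: 50, lambda1: 0.0018660, lambda2: 0.0021810}
  - {start: 50, end: 55, lambda1: 0.0022110, lambda2: 0.0036550}
  - {start: 55, end: 60, lambda1: 0.0027210, lambda2: 0.0060280}
  - {start: 60, end: 65, lambda1: 0.0033480, lambda2: 0.0097610}
  - {start: 65, end: 70, lambda1: 0.0039230, lambda2: 0.0148220}
  - {start: 70, end: 75, lambda1: 0.0041780, lambda2: 0.0230220}
  - {start: 75, end: 80, lambda1: 0.0043990, lambda2: 0.0370810}
  - {start: 80, end: 85, lambda1: 0.0042210, lambda2: 0.0660200}
  - {start: 85, end: 90, lambda1: 0.0041090, lambda2: 0.1440280}
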