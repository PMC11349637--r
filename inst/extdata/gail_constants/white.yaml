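# Gail-model constant block: White (also serves other/unknown via alias).
# All rates are per woman-year; age bands are [start, end) and tile [20, 90).
version: "1.0"
race_group: white
provenance: >
  Log relative-risk coefficients, atypical-hyperplasia multipliers and the
  attributable-risk adjustment from the original 1989 BCDDP case-control
  model for White women; composite invasive breast-cancer incidence and
  non-breast-cancer competing mortality from the SEER 1983-1987 White
  female rates distributed with the NCI Breast Cancer Risk Assessment Tool
  (bcrisktool.cancer.gov).
# Log relative risks per category step; interactions as published.
beta:
  n_biopsies: 0.5292641686
  age_at_menarche: 0.0940103059
  age_at_first_birth: 0.2186262218
  n_relatives: 0.9583027845
  biopsies_x_age_ge50: -0.2880424830
  first_birth_x_relatives: -0.1908113865
# Multiplier applied to the relative risk according to biopsy pathology.
hyperplasia_rr:
  present: 1.82
  absent_with_biopsy: 0.93
  unknown_or_no_biopsy: 1.00
# 1 - attributable risk: scales composite incidence down to the
# baseline-category population, by age stratum.
one_minus_ar:
  age_lt50: 0.5788413
  age_ge50: 0.5788413
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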