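# transcreen

Decision support for chest/breast cancer screening in transgender and
non-binary adults, for primary-care clinicians and health-services
researchers. The package combines two established instruments:

1. **A Gail-model (BCRAT-style) absolute-risk engine.** Relative risk is
   proportional-hazards in form,
   `RR = exp(β₁N_B + β₂A_M + β₃A_F + β₄N_R + β₅N_B·1[age≥50] + β₆A_F·N_R) · R_hyp`,
   over age at menarche, age at first live birth, breast biopsies,
   atypical hyperplasia and first-degree family history. Absolute risk
   over an age interval combines the attributable-risk-adjusted composite
   incidence with competing mortality via the exact piecewise-constant-
   hazard closed form
   `P = Σⱼ h₁ⱼ/(h₁ⱼ+h₂ⱼ) · (1 − e^−(h₁ⱼ+h₂ⱼ)Δⱼ) · Sⱼ`.
   Constants ship as versioned, provenance-tagged YAML tables (one per
   race/ethnicity group) and are validated on load.
2. **An appropriateness-criteria decision table** with eight variants
   keyed on gender identity arm, age, cumulative gender-affirming hormone
   exposure, chest surgical history, and the named Gail risk tier
   (lifetime <15% average, 15–20% intermediate, ≥20% high; 5-year ≥1.67%
   elevated) — producing mammography/ultrasound ratings on the
   "usually appropriate / may be appropriate / usually not appropriate"
   scale. Bilateral mastectomy dominates every other condition; profiles
   the table does not cover return an explicit `NO_MATCH` with a
   re-evaluation hint instead of a silent default.

The same pipeline is exposed three ways: the direct API, a 16-item
yes/no questionnaire flow whose terminal states provably agree with the
direct classifier, and a batch CSV scorer. A seeded synthetic-cohort
generator makes everything testable without patient data.

## Worked example

```r
library(transcreen)

p <- risk_factor_profile(45, "12to13", "25to29_or_nulliparous",
                         n_biopsies = 1, atypical_hyperplasia = "absent",
                         n_relatives = 1, race_group = "white")
gail_risk(p)
#> Gail risk estimate: 5-year 2.54%, lifetime 21.35%
#>   tiers: high (three-tier), higher_than_average (two-tier)

tp <- trans_profile("transfeminine", age = 45, hormone_years = 8)
recommend(classify_variant(tp, gail_risk(p)))
#> Screening recommendation [variant V2, transwoman arm]
#>   mammography: usually appropriate
#>   ultrasound:  usually not appropriate
#>   Variant 2 (transwoman arm): age >= 25, past or current hormone use >= 5 years,
#>   higher than average risk (Gail model).
```

A 45-year-old transfeminine patient with 8 years of hormone therapy,
one benign biopsy and an affected first-degree relative projects a 2.54%
5-year and 21.35% lifetime invasive-cancer risk, placing her in the
higher-than-average tier; the table then rates screening mammography
"usually appropriate" (variant 2).

The questionnaire reaches the same endpoint from yes/no answers:

```r
res <- run_answer_string("YYYYYYYNNNNNNNNN")  # item k answered by char k
res$recommendation$variant$id   # "V1"
```

and `decision_table()` renders the whole rule set, including the
explicit `NO_MATCH` cells. A thin CLI wraps these functions:

```sh
Rscript inst/cli/transcreen.R interactive
Rscript inst/cli/transcreen.R batch --input cohort.csv --output scored.csv
Rscript inst/cli/transcreen.R cohort --n 100 --seed 7 --output cohort.csv
```

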