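---
title: "Methods: combined Gail-model risk projection and transgender screening appropriateness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined Gail-model risk projection and transgender screening appropriateness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcreen)
```

## The problem

Breast/chest cancer screening guidance was built around cisgender
populations, and primary-care clinicians are often unsure which imaging
modality, if any, to order for transgender and non-binary patients. The
clinically established answer combines two instruments: a validated
absolute-risk model (the Gail model, the basis of the NCI Breast Cancer
Risk Assessment Tool) to place the patient in a named risk tier, and an
appropriateness-criteria table — keyed on gender identity, age, cumulative
gender-affirming hormone exposure and chest surgical history — that turns
the tier into a modality recommendation. `transcreen` implements that
combination as a library, a 16-item yes/no questionnaire, and a batch
scorer, so the logic can be exercised, audited, and tested end to end.

## The absolute-risk engine

### Relative risk

The model is proportional-hazards in form. Six risk factors enter as
category indices (baseline index 0): age at menarche (≥14, 12–13, <12),
age at first live birth (<20, 20–24, 25–29 or nulliparous, ≥30), number of
breast biopsies (0, 1, ≥2), and number of first-degree relatives with
breast cancer (0, 1, ≥2). The relative risk versus the all-baseline
profile is

$$\mathrm{RR} = \exp\Big(\beta_1 N_B + \beta_2 A_M + \beta_3 A_F +
\beta_4 N_R + \beta_5 N_B \cdot \mathbb{1}[\text{age} \ge 50] +
\beta_6 A_F N_R\Big) \cdot R_{\mathrm{hyp}},$$

with the two published interaction terms (biopsies × age stratum, first
birth × relatives) and the biopsy-pathology multiplier
$R_{\mathrm{hyp}}$ (1.82 when atypical hyperplasia was found, 0.93 when
all biopsies were benign without hyperplasia, 1 otherwise). "Unknown"
always scores as the baseline category, so missing history can never
inflate risk; in particular, transfeminine profiles without natal
menstrual or obstetric history score those factors at baseline.

### Absolute risk with competing mortality

Composite invasive-cancer incidence $\lambda_1$ and competing
(non-breast-cancer) mortality $\lambda_2$ are piecewise constant on
5-year age bands tiling [20, 90). Incidence is first scaled by the
attributable-risk adjustment $1-\mathrm{AR}$ (so the baseline hazard
refers to the baseline-category population) and by the age-stratum
relative risk. Over a projection interval cut at every band edge (age 50,
where the stratum switches, is itself an edge), each segment $j$ of width
$\Delta_j$ contributes the exact closed form

$$P_j \;=\; \frac{h_{1j}}{h_{1j}+h_{2j}}
\left(1 - e^{-(h_{1j}+h_{2j})\Delta_j}\right) S_j,
\qquad S_{j+1} = S_j\,e^{-(h_{1j}+h_{2j})\Delta_j},$$

summed to give the probability of developing invasive breast cancer in
the interval while alive. No numeric quadrature is involved in the
engine itself; the test suite's independent oracle is a midpoint Riemann
integrator on a 0.01-year grid aligned to band edges, and the two agree
to well under $10^{-6}$ across seeded random profiles. Degenerate inputs
are handled explicitly: an empty interval returns exactly 0, zero hazards
return exactly 0, intervals outside [20, 90) are clipped with a warning,
and a reversed interval is an error.

### Constants and their provenance

No constants are invented here: the log relative risks, hyperplasia
multipliers, $1-\mathrm{AR}$ factors and the SEER 1983–87 composite
incidence/mortality bands ship as versioned YAML blocks under
`inst/extdata/gail_constants/`, one file per race/ethnicity group, each
with a provenance note, and are validated on load (bands must tile
[20, 90), hazards must be non-negative, every coefficient must be
present). Race-specific coefficient blocks (the CARE model for Black
women, the San Francisco Bay Area study for US-born Hispanic women, the
Asian American Breast Cancer Study) select different $\beta$ and
$1-\mathrm{AR}$ values; `other`/unknown race aliases the White block, the
convention of the NCI tool.

**Limitation:** this release ships the SEER 1983–87 White incidence and
competing-mortality table for *all* race groups; race-specific hazard
tables are a planned extension. This shifts the absolute-risk scale for
non-White groups, but not the decision-table logic, which consumes only
the categorical tier.

### Risk tiers

The decision table names tiers without defining them numerically, so the
package uses the standard screening convention, exposed through
`gail_thresholds()` and overridable in configuration: lifetime risk
(projection to age 90) below 15% is *average*, 15–20% *intermediate*, 20%
and above *high*; a 5-year risk of 1.67% or more marks a profile
*higher than average* on its own. Every boundary is closed on the lower
side — a risk exactly at a threshold falls in the upper tier — and the
test suite verifies exactly one category flip per threshold at ±1 ulp.
The transfeminine arm of the table speaks the two-tier vocabulary
(average / higher than average), the transmasculine arm the three-tier
one; "higher than average" is treated as intermediate ∪ high.

## The decision table

The eight variants are encoded declaratively (`rule_set()`), matched in
priority order, and rendered by `decision_table()`:

```{r table}
decision_table()
```

Design choices where the printed table is silent:

* **Totality.** The printed table is not total (no row covers, say, a
  30-year-old average-risk transfeminine patient with 5+ years of
  hormones). Rather than inventing a default, unmatched profiles return
  `NO_MATCH` with a reason code and, for age-related gaps, the age at
  which the profile would first qualify — surfaced as a re-evaluation
  hint.
* **Mastectomy dominance.** "Double bilateral mastectomy, any risk →
  screening usually not appropriate" is read literally and applied in
  both arms, overriding even a high Gail tier; some experts disagree with
  withholding screening after top surgery, and that controversy is
  documented here rather than resolved. On the transfeminine arm the rule
  is an extrapolation and is flagged as such.
* **Non-binary identities.** The table has two arms; non-binary profiles
  are routed by sex assigned at birth and every such recommendation
  carries an `extrapolated` flag.
* **Rating order.** `usually_appropriate` > `may_be_appropriate` >
  `usually_not_appropriate` ≥ `not_indicated`. The two lowest labels
  share a rank — both mean no screening is being recommended — which is
  what makes the table's monotonicity guarantees (raising age or risk
  tier never lowers a rating) hold at the `NO_MATCH` boundary.
* **Inclusive thresholds.** All "≥" cut points are inclusive; hormone
  exposure partitions at exactly 5.0 years.

## The questionnaire flow

The 16 yes/no items form a fixed acyclic branch graph: natal sex, then
(on the transfeminine arm) identity and hormone items, or (on the
transmasculine arm) surgery items first — so a bilateral mastectomy
terminates the flow after two questions, at which point no later answer
could change the recommendation. Age enters as bracketed items (≥25,
≥30, ≥40) mapped to the lowest consistent integer age, a deliberate
coarsening relative to the direct API; likewise the menarche and
first-birth items collapse the middle categories ("no" lands on the
baseline). Menstrual/obstetric items are asked on both arms so the graph
stays fixed; respondents without that history answer "no" and score at
baseline. Terminal states rebuild both profile objects, run the Gail
engine, and call the same classifier as the direct API — so flow and
classifier cannot drift apart by construction, and
`enumerate_paths()` verifies it anyway: the flow has 1,921 distinct
terminal paths (cross-checked against an independent tree-walk count and
a replay of all $2^{16}$ answer strings), none longer than 14 items,
none divergent.

## The synthetic cohort generator

`sample_cohort()` exists for coverage, not epidemiology: uniform ages
over 18–90; hormone duration 0 with probability 0.6, otherwise uniform
on (0, 10] years (so roughly one record in five carries the ≥5-year
exposure that activates the hormone-dependent rows); every surgery state
represented on both natal-sex arms; and unremarkable Gail-factor
prevalences (70/25/5% for 0/1/≥2 affected relatives, 80/15/5% for
biopsies, 10% atypical hyperplasia given a biopsy). It emulates the
*structure* of real intake data — field domains, invariants such as
"hyperplasia implies a biopsy", identity-consistent natal sex — and none
of its epidemiology: passing tests demonstrate correctness of the logic
on realistic record shapes, not calibration to population incidence.
Sampling is seeded, restores the caller's RNG state, and round-trips
through the batch CSV schema byte-for-byte.

## Numerical and testing choices

* Problem sizes: the exhaustive property grid is ages 18–90 × hormone
  years 0–40 × 3 surgery states × 3 tiers × 4 identities (107,748
  profiles, all classified vectorized); the engine-vs-integrator check
  uses 100 seeded random profiles over random whole-year horizons.
* The integrator oracle uses the midpoint rule with step 0.01 years
  aligned to band edges; with piecewise-constant hazards the cumulative
  hazard at midpoints is then exact and the quadrature error is orders of
  magnitude below the 1e-6 comparison tolerance.
* Ages are integers at every interface and real-valued internally;
  projection uses exact exponentials, never per-year rounding.

## Known limitations

* The Gail model omits genetic status (BRCA1/2), extended family history
  and lifestyle factors, is most accurate for 5-year projection, and was
  not developed on transgender cohorts; published systematic reviews
  suggest it may over-estimate risk for transgender patients. The tool is
  decision support for *screening imaging choice*, not a diagnosis or a
  substitute for clinical judgment.
* Hormone exposure is consumed only by the decision table, never fed into
  the Gail computation itself.
* Shared hazard table across race groups (above).
* MRI is out of scope: the underlying criteria table contains no MRI row.
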