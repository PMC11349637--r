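Package: transcreen
Title: Transgender Chest/Breast Cancer Screening Decision Support
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision support for chest/breast cancer screening in transgender
    and non-binary adults. Combines a Gail-model (Breast Cancer Risk Assessment
    Tool) absolute-risk engine -- proportional-hazards relative risks over six
    classical risk factors, piecewise-constant baseline and competing-mortality
    hazards, and an attributable-risk correction -- with an appropriateness-
    criteria decision table keyed on gender identity, age, cumulative hormone-
    therapy duration, chest surgical history and Gail risk tier. Exposes the
    risk engine and classifier directly, as a 16-item yes/no questionnaire
    flow, and as a batch scorer over CSV cohorts; includes a seeded synthetic-
    cohort generator so every component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
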