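Package: calfclim
Title: Climatic Housing Environment and Growth of Pre-Weaned Dairy Calves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cold exposure of pre-weaned dairy calves
    from hourly barn climate records and relating it to early-life growth.
    Computes a wind- and humidity-adjusted effective temperature for every
    recorded hour, an age-dependent lower critical temperature (LCT) for
    every calf-day, and the proportion of each housing phase spent below
    the LCT; derives daily liveweight gain (DLWG) for the individual-hutch
    phase (interval rate) and the group-pen phase (least-squares slope of
    weight on age); classifies Wisconsin health scores; applies the study
    eligibility filters; and fits the screening, backward-elimination,
    linear mixed model and Tukey post-hoc chain. A seeded synthetic-data
    generator reproduces the statistical structure of a year-long cohort so
    the whole chain can be exercised and its parameters recovered without
    access to farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    truncnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
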