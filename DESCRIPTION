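Package: gaitspring
Title: Planar Inverse Dynamics and Achilles Tendon Spring Mechanics for Gait Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for sagittal-plane inverse dynamics of
    the human lower limb during locomotion. Computes net joint moments by the
    free-body (link-segment) method from marker trajectories and force-plate
    records, resolves extensor muscle forces with bi-articular corrections,
    decomposes joint work into positive and negative components, and summarises
    the spring-like behaviour of the ankle with the specific net work (SNW)
    statistic. Estimates Achilles tendon stress, strain, length change and
    Hookean elastic energy storage from tendon morphometrics, and analyses
    cohorts with one-tailed Pearson correlations and subject-random-intercept
    mixed models on z-scored variates. Includes a synthetic gait-trial
    generator (walk to sprint) with forward-constructed ground truth so the
    whole pipeline is testable without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    signal,
    pracma,
    lme4,
    yaml,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
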