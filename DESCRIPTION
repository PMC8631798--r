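Package: divtrace
Title: Quantification and Binomial Correction of Dual-Colour Monosynaptic
    Rabies Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dual-colour monosynaptic rabies tracing of
    premotor spinal neurons. Provides a seeded simulator of virtual spinal-cord
    premotor cohorts with known ground-truth divergence and Bernoulli per-jump
    viral labelling; counting and spatial-mapping stages (central-canal
    coordinate normalisation, quadrant assignment, section subsampling,
    divergence-rate summaries, soma-area group statistics, binned density
    profiles); and a binomial double-infection model that corrects observed
    double-labelling rates to true divergence rates, in closed form and by
    Monte Carlo, with parametric-bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
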