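Package: survMCTP
Title: Multiple Contrast Tests for Right-Censored Survival Data Under
    Non-Proportional Hazards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multiple contrast test procedures (MCTPs) for comparing k
    right-censored survival samples when hazards may be non-proportional or
    crossing.  Implements Bonferroni-adjusted weighted log-rank tests,
    Bonferroni-adjusted multi-directional (mdir) permutation tests combining
    several weight functions, a maximum test over weighted log-rank
    statistics calibrated by an equicoordinate multivariate-normal quantile,
    and a wild-bootstrap procedure built on pooled cumulative-hazard
    contrasts with Rademacher or centered-Poisson multipliers.  Ships a
    Monte-Carlo harness for family-wise error rate and power studies under
    configurable survival scenarios (proportional, non-proportional,
    crossing and mixed hazards) with calibrated uniform censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mvtnorm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
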