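Package: woasim
Title: Simulation and Multilevel Analysis of Weight-of-Advice Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing judge-advisor-system
    (JAS) trials of prognostic advice-taking. Provides blocked 1:1
    randomisation lists, a synthetic-cohort generator emulating a two-arm
    vignette study of clinicians' two-week survival estimates, the
    weight-of-advice (WOA) statistic with capping, tie-exclusion, per-protocol
    filtering and ordinal binning, descriptive summary tables, and
    from-scratch multilevel inference: a random-intercept linear model fitted
    by profiled REML with Wald tests, and a proportional-odds cumulative-logit
    model with a participant random intercept integrated by adaptive
    Gauss-Hermite quadrature. Includes a file-based pipeline (simulate,
    analyse, report) with full seed provenance for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    lme4,
    MASS,
    optparse
Config/testthat/edition: 3
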