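Package: svyicc
Title: Intraclass Correlation and Design Effects for Single-Stage Cluster
    Surveillance Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation pipeline for subject-level data collected under
    single-stage cluster sampling, as used in multicenter surveillance of
    severe maternal morbidity. Computes per-variable prevalence with the
    cluster ratio estimator, the one-way ANOVA intraclass correlation
    coefficient (ICC) with an asymptotic confidence interval, the empirical
    design effect (DEFF), and cluster-corrected sample-size recalculation.
    Includes a beta-binomial generator of clustered binary cohorts with known
    prevalence and ICC for validation, a declarative variable-dichotomization
    configuration, and a reporting layer with an embedded reference table of
    published ICC/DEFF values from a 27-center, 9,555-subject maternal
    morbidity surveillance network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
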