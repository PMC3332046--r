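Package: adcea
Title: Cost-Effectiveness Modelling of Early Alzheimer's Disease Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A Markov cohort decision-analytic model of Alzheimer's disease
    progression coupled to diagnostic-strategy decision trees, for comparing
    the cost-effectiveness of standard cognitive diagnosis, standard MRI, and
    MRI enhanced with an amyloid-binding contrast agent, in both a memory-clinic
    setting and population screening programmes. Provides six-month cycle
    conversion of annual transition matrices by principal matrix square root,
    societal-perspective cost and QALY accumulation with discounting, ICER and
    dominance ranking with net-monetary-benefit selection, and a sensitivity
    suite covering univariate sweeps, triangular-prior probabilistic
    sensitivity analysis, cost-effectiveness acceptability curves, and partial
    rank correlation coefficients.
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
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
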