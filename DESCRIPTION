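Package: mmselect
Title: Multicompound Multitarget Selectivity Scoring for Kinase Inhibitor Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and optimizes the selectivity of kinase inhibitors and
    inhibitor mixtures from compound-by-kinase potency matrices. Cumulative
    target occupancy of a mixture is computed with a competitive-binding
    model, off-target activity profiles are smoothed, binned and compared to
    a user-shaped penalty distribution with the Jensen-Shannon distance, and
    component concentrations are optimized by a branch-and-bound search so
    that the most selective single inhibitor or inhibitor combination for a
    target set can be nominated. Includes a synthetic-data engine for
    bootstrapped inhibitor panels, selectivity set-size scans and fold-error
    Monte-Carlo studies, plus classical selectivity metrics (Gini
    coefficient, S-score, relative selectivity factor) for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
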