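Package: lpdscore
Title: Combination Scoring of Lymphoid Follicles for Ocular Adnexal
    Lymphoproliferative Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a semi-quantitative immunohistochemistry scoring
    method for the differential diagnosis of ocular adnexal
    lymphoproliferative disease (reactive follicular hyperplasia, atypical
    lymphoid hyperplasia, and MALT lymphoma): CD23/IgD expression scoring
    from percent-positive rates averaged over five high-power fields,
    lymphoid-follicle structure scoring, and their combination score.
    Provides the accompanying clinicopathological statistical battery
    (chi-square, Fisher exact, summary-statistic and raw t tests, Pearson
    correlation, pairwise comparisons at the alpha/n corrected level),
    threshold-based diagnostic evaluation against IgH-clonality results
    with group sensitivities, a packaged reference count table from the
    125-patient cohort, and a seeded synthetic cohort generator with
    correlated CD23/IgD biomarkers for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
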