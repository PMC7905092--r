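Package: fluencysvd
Title: Text-Mining Analysis of Category-Fluency Data via Singular Value Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating semantic memory structure from category-fluency
    (semantic verbal fluency) transcripts. Cleans raw token lists (repetitions,
    intrusions, proper nouns), builds binary item-by-subject occurrence matrices,
    decomposes them by singular value decomposition with a cumulative
    singular-value dimensionality rule, and summarises inter-item structure as
    cosine similarities and cosine profiles. Group change is quantified by
    correlating flattened cosine pair vectors across conditions and testing
    dependent overlapping correlations with Meng's z. Includes summary-statistic
    demographic tests (pooled and Welch t, Levene, 2x2 chi-square), a seeded
    synthetic fluency-cohort generator with known cluster structure for
    verification, and a full pipeline from transcripts (or a synthetic
    configuration) to a serialisable analysis report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
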