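Package: panelagree
Title: Chance-Corrected Agreement Optimization and Rater Selection for
    Expert-Labelled Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating expert-labelled databases from large rating
    panels of nominal (typically binary) features. Implements multi-rater
    Gwet's AC1 chance-corrected agreement with missing-data support and a
    delete-one-item jackknife standard error, per-rater intrarater (test-retest)
    agreement, leave-one-out identification of discordant raters through
    Spearman-Brown predicted reliability intervals, iterative optimization of
    interrater agreement to the "substantial" benchmark, per-rater disagreement
    scoring, and three rater-selection policies compared by rank-based or
    heteroscedastic post hoc tests. Includes a fully seeded synthetic
    rating-panel generator with planted discordant raters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
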