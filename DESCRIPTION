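Package: flavorwatch
Title: Social-Media Surveillance of E-Cigarette Liquid Flavor Mentions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An infoveillance pipeline for monitoring electronic-cigarette
    liquid (e-liquid) flavor discussion on social media. Provides a
    hierarchical flavor-keyword taxonomy with classification rules,
    staged corpus filtering (topic keywords, promotion removal,
    precision/recall keyword denoising, single-flavor subsetting),
    monthly mention-trend normalization, threshold-based sentiment
    classification with an injectable valence scorer, pooled
    two-proportion z-tests with Bonferroni adjustment, and a seeded
    synthetic-corpus generator with a ground-truth ledger for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
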