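Package: termnet
Title: Seed-Term Co-Occurrence Networks and Pre/Post Cross-Tabulation for
    Clinical Record Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Text-mining pipeline for corpora of short clinical records
    written around an anchor ("seed") term, such as ward-pharmacist notes
    mentioning antimicrobials.  Provides part-of-speech filtering and
    proper-noun anonymization over a pluggable tokenizer contract,
    terminology standardization (compound merging, controlled-vocabulary
    synonyms, exclusion lists), compound-term discovery by log-frequency
    ratio (FLR) scoring, Dice-coefficient co-occurrence networks centered
    on the seed term with Louvain community detection and maximum-weight
    spanning trees, Ward hierarchical clustering of network terms on
    1 - Dice, and per-cluster pre/post-intervention cross-tabulation with
    odds ratios, confidence intervals and Fisher's exact test.  Includes a
    synthetic two-period corpus generator with planted term clusters and
    planted period odds ratios so every stage can be validated without
    access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
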