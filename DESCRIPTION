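Package: hetscreen
Title: Quantitative Analysis of Multi-Domain Heterochromatin Silencing Screens
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for colony-array heterochromatin silencing
    screens in fission yeast. Converts colony sizes from ura4+ reporter screens
    at four heterochromatin domains (CEN, MAT, SUBTEL, TEL) into plate-median
    normalized relative growth, combines the -URA and +FOA selective readouts
    into a per-replicate combined score, calls silencing and anti-silencing
    hits with a one-sample t-test plus effect-size thresholds, calibrates the
    caller against gold-standard gene lists and transcript fold-changes,
    clusters phenotypic profiles by consensus k-means with within-cluster
    hierarchical ordering, tests protein-complex coherence of profiles with a
    label-permutation test, and quantifies single-cell reporter ON/OFF states
    from flow-cytometry exports. Includes a synthetic-data generator with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
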