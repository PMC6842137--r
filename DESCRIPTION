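Package: synloss
Title: Synteny-Confirmed Screening for Gene Loss Across Species Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies genes of a reference species whose orthology or local
    gene synteny is disrupted in one predefined set of species while both are
    retained in another set. The elementary presence test requires an ortholog
    of the focal gene together with a configurable number of neighbouring
    "witness" gene pairs conserved within bounded genomic vicinities; gene
    selection over species sets is expressed in a small Boolean predicate
    language with per-set thresholds, and calls from several orthology sources
    can be combined by voting. Includes per-gene maximal thresholds and a
    quality index for ranking predictions, longevity-quotient utilities for
    building species fractions from life-history data, and a deterministic
    synthetic-fixture generator with planted gene losses for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io.R'
    'neighbors.R'
    'presence.R'
    'predicate.R'
    'screen.R'
    'longevity.R'
    'fixtures.R'
    'config.R'
    'synloss-package.R'
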