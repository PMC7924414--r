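Package: sitematch
Title: Enrichment Analysis of Genomic Position Sets with Covariate-Matched
    Background Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Relates large sets of single-base genomic positions (virus or
    transposon integration sites, protein binding sites) to annotation
    tracks via fold-change enrichment, chi-square and Kolmogorov-Smirnov
    tests with Bonferroni correction.  Its central feature is the
    construction of background (control) site sets that are matched to the
    signal sites' distribution over user-chosen covariates -- membership in
    a track, distance to track features (e.g. restriction sites), track
    scores, or sequence motif context -- singly or jointly, so that known
    technical or biological biases cancel out of the comparison.  Includes
    a synthetic-fixture generator (genomes, tracks, motif-constrained site
    sets with known ground truth), batch and hotspot analyses, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    optparse,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
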