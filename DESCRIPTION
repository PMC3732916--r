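Package: coexflow
Title: Cross-Species Gene Co-Expression Network Construction and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses gene co-expression networks from
    multi-condition expression compendia, following the hard-threshold
    absolute-Pearson approach with automatic threshold selection by
    scale-free model fit at a target network density. Includes
    differential-gene selection with delta-method variances, Kleinberg
    (HITS) hub scoring with top-fraction hub calling, k-hop neighborhood
    extraction, GO-term hypergeometric enrichment with cross-species
    conservation classes, marker-correlation gene grouping, IUPAC promoter
    motif scanning with Fisher enrichment, distance-based neighbor-joining
    phylogenetics with bootstrap consensus, and a synthetic-data generator
    that emulates multi-condition compendia with planted co-expression
    modules, bridging hub genes, annotations, promoters and alignments for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse,
    withr
Config/testthat/edition: 3
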