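Package: fucopul
Title: Genome-Resolved Profiling of Sulfated Polysaccharide Degraders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A genome-resolved metagenomics toolkit for identifying and
    profiling bacterial specialists that degrade fucose- and
    rhamnose-containing sulfated polysaccharides. Implements MAG quality
    scoring and filtering, ANI-graph dereplication with representative
    selection, truncated-average-depth abundance normalised to community
    rpoB depth, dual-evidence CAZyme/sulfatase/peptidase content
    profiling, gene-neighbourhood classification of polysaccharide
    utilization loci (PULs), bacterial microcompartment (BMC) locus
    detection, methyl-pentose pathway completeness scoring, and NSAF
    metaproteome mapping. Ships a synthetic mock-community generator with
    planted ground truth so the whole pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    GenomicRanges,
    IRanges,
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
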