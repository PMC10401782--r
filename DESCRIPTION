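Package: syntelogr
Title: Syntelog-Based Pan-Genome Construction and Introgression Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a pan-genome of syntelog groups (SGs) across many annotated
    genomes by synteny-aware clustering: protein best hits are collapsed for
    individual-specific tandem duplicates, chained into collinear blocks by
    dynamic programming, and merged iteratively onto a framework genome.
    Classifies SG occupancy (core, soft-core, dispensable, private), computes
    pan-genome growth curves and presence-absence biases between populations,
    assigns ancestral haplotype labels per SG by a group-priority scheme,
    quantifies inter-population haplotype divergence (HDG), and detects
    candidate introgression blocks as runs of lowly divergent SGs whose
    clustering is assessed by a permutation test. Ships a synthetic panel
    generator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
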