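Package: ndhaudit
Title: Audit of Plastid ndh Gene Degradation Across Annotated Plastomes
Version: 0.1.0
Authors@R:
    person("Plastome", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to audit the eleven plastid ndh genes (ndhA-ndhK) across a
    cohort of annotated plastome records. Reads GenBank flat files, resolves
    gene and CDS features (including inverted-repeat duplicates and
    origin-spanning features on circular molecules) into per-gene
    observations, infers per-gene reference lengths by exact-length consensus
    with a two-pass outlier-excluding mean as fallback, classifies each gene
    in each sample as functional, truncated (internal premature stop codon),
    pseudogenized (length outside 80-120% of the reference) or lost (absent
    or below 20% of the reference), concatenates per-gene alignments into a
    partitioned supermatrix with variable-site and missing-data statistics,
    maps gene-status patterns onto a phylogeny to count minimal independent
    loss events by parsimony, and simulates annotated plastome cohorts with
    planted gene states for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
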