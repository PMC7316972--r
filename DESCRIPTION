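Package: scCloneCNV
Title: Sub-Clone Deconvolution from Shallow Single-Cell DNA Copy-Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves sub-clonal structure in shallow single-cell whole-genome
    DNA sequencing of tumor cell lines. Per-cell binned read counts are
    segmented and scaled to integer copy-number profiles, converted into a
    binary cells-by-events matrix by size/confidence filtering and reciprocal-
    overlap merging, and clustered by discriminant analysis of principal
    components (DAPC) with BIC model selection. Clusters are merged into major
    groups by consensus over large hallmark events, and group-level pseudo-bulk
    analyses (log2 fold change against a matched normal, segment-level
    loss-of-heterozygosity from heterozygous-SNP allele fractions, and
    anomalous read-pair breakpoint clustering with split-read refinement)
    characterize each sub-clone. A seeded synthetic-cohort generator encoding
    a four-clone near-triploid COLO829-like model makes the whole pipeline
    testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
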