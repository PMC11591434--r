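Package: rohsignal
Title: Runs of Homozygosity, Diversity, and Selection-Signature Scans for SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Population-genetic analysis of multi-population bi-allelic SNP
    panels such as those produced by reduced-representation sequencing of
    livestock breeds. Provides VCF input/output and filtering (call rates,
    monomorphic removal, windowed linkage-disequilibrium pruning),
    per-population diversity statistics (segregating sites, minor allele
    frequency, private alleles, heterozygosity, nucleotide diversity,
    Watterson's theta, and their difference), population structure (AMOVA,
    Weir-Cockerham Fst with locus bootstrap, Euclidean distances,
    neighbor-joining trees, principal coordinate analysis), a window-based
    runs-of-homozygosity scanner with genomic inbreeding coefficients and
    ROH-incidence islands, a neutral-Fst outlier test in the style of
    OutFLANK, and a selection-signature scan intersecting high-ROH-incidence
    loci with Fst outliers. A Balding-Nichols synthetic-data generator with
    machine-readable ground truth makes every stage testable without
    controlled-access sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
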