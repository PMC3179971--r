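Package: haplolink
Title: Haplotype-Sharing Linkage Analysis for Disease-Gene Mapping in Pedigrees
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Whole-genome parametric linkage mapping that uses shared
    haplotype fragments, rather than individual SNPs, as markers. Dense
    biallelic SNP genotypes of a single family (linkage PED/MAP format) are
    decomposed into nuclear trios and phased by Mendelian rules; the parental
    haploids that must co-segregate with a dominant or recessive disease
    (affected haploids, "aHaps") are collected; a tolerant sliding window
    locates the genomic regions over which all aHaps carry one identical
    haplotype; and each candidate region is scored with a two-point LOD score
    that treats the shared haplotype as a single fully informative marker.
    Handles incomplete penetrance through paired candidate haploids, flags
    possible large deletions with a loss-of-heterozygosity run test, writes
    BED/TSV/JSON region files plus a self-contained hypertext report and a
    genome-wide LOD figure, and ships a seeded gene-dropping pedigree
    simulator for validation data with known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
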