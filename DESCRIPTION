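Package: hybriqc
Title: Marker-Based Quality Control for Parental Fingerprinting and F1
    Hybridity Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality-control analysis of biallelic SNP genotyping data from
    breeding-program crossing blocks. Reads KASP-style genotype call tables
    (call-grid CSV/TSV or HapMap dialect), summarises per-marker allele
    frequencies, heterozygosity, missingness and polymorphism information
    content, scores marker polymorphism and efficiency between the parents of
    each cross, authenticates putative F1 progenies as true hybrids or selfs
    from heterozygosity at informative loci, and characterises parental
    relatedness through pairwise Euclidean genetic distances, Neighbor-Joining
    trees and principal component analysis with per-marker contributions.
    Includes a synthetic-cohort generator that emulates a cowpea crossing
    programme (near-homozygous inbred parents, sister-line males, selfing
    contamination, per-call missingness) with ground-truth labels, so every
    pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
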