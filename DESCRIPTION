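Package: mendelaudit
Title: Mendelian Error Auditing and Classification for SNP Array Trio Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Mendelian inconsistencies in parent-offspring trios
    genotyped on SNP arrays and assigns each to one of eight origin/allele
    classes (Trio, Father, Mother or Offspring crossed with the major or
    minor allele). Computes per-locus statistics (minor allele frequency,
    observed and expected heterozygosity, F_IS, the exact Hardy-Weinberg
    test), dataset-level error rates per locus and per allele, and detects
    allele-drop-out and allele-drop-in loci characteristic of null and
    partial-null alleles. Overlaps error loci with CNV, SINE and LINE
    interval tracks, and quantifies the SNP-loss versus mismatch-removal
    trade-off of MAF, Hardy-Weinberg and heterozygote-deficiency filters.
    Includes a pedigree gene-drop simulator with parameterised error
    mechanisms and a truth table so every stage can be validated on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
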