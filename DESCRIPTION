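Package: cas12mux
Title: Multiplex Cas12a Amplicon Genotyping and crRNA Array Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for CRISPR-Cas12a multiplex knockout experiments in plants:
    calling indel alleles from amplicon deep-sequencing read pools, classifying
    per-gene zygosity (homozygous, biallelic, heterozygous, chimeric) with
    read-fraction thresholds, aggregating calls across targeted genes into
    multiplex genotypes with in-frame (3x) indel annotation, associating
    genotypes with seed-germination phenotypes, and tallying population editing
    efficiencies. Also implements the companion design computations: TTTV PAM
    scanning, dual-targeting of homologous genes via PAM-distal mismatches,
    off-target site enumeration, tandem crRNA array assembly under two U6
    promoters, and Golden Gate oligo rendering with in-silico ligation. A
    synthetic population generator with known per-gene editing outcomes makes
    the whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
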