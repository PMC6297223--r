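Package: cnvhic
Title: CNV-Aware and Haplotype-Resolved Hi-C Contact Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying how a heterozygous multi-megabase
    deletion reshapes chromatin organisation. Builds binned Hi-C contact
    matrices from read-pair files, computes deletion-versus-control
    fold-change maps, assigns reads to homologous chromosomes through phased
    SNVs to produce per-homolog contact maps, calls A/B compartments and
    topological domains, tests inter-chromosomal contacts for differential
    interaction with permutation controls, and integrates ChIP-seq,
    RNA-seq, allele-specific expression and 3D FISH measurements. Ships a
    synthetic diploid cohort generator with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
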