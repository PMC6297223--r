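#!/usr/bin/env Rscript
# RNA/ChIP integration: differential expression stand-in, site Z-scores,
# binned Fisher enrichment, peak-TSS assignment, the four-group
# permutation coupling tests, direct expression-signal correlation,
# allele-specific expression, and bin-pair signal correlation.

suppressMessages({library(cnvhic); library(data.table)})
seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
cohort <- readRDS("scratch/cohort.rds")
cfg <- cohort$config
bins <- make_bins(cfg$genome, 5e5)

de <- simple_de_standin(cohort$expression)
fwrite(de[, .(gene_id, chrom, tss, log2fc, p, fdr_p, significant, up)],
       "results/differential_expression.tsv", sep = "\t")
enr <- binned_enrichment(de[, .(chrom, pos = tss, significant)], bins)
fwrite(enr, "results/de_binned_enrichment.tsv", sep = "\t")
top <- enr[!is.na(p)][order(p)][1:5]
message("top DE-enriched bins: ",
        paste(sprintf("%s:%.1f-%.1f Mbp", top$chrom, top$start / 1e6,
                      top$end / 1e6), collapse = "; "))

coup <- list()
for (mark in c("H3K27ac", "H3K27me3")) {
  z <- zscore_differential_sites(cohort$chip[[mark]])
  fwrite(z[, .(site_id, chrom, start, end, log2fc, zscore, significant)],
         paste0("results/chip_zscores_", mark, ".tsv"), sep = "\t")
  a <- assign_peaks_to_tss(cohort$chip[[mark]], de)
  a <- a[gene_id %in% de$gene_id]
  zs <- setNames(z$zscore, z$site_id)
  ix <- match(a$gene_id, de$gene_id)
  coup[[mark]] <- four_group_coupling_test(zs[a$site_id], de$significant[ix],
                                           de$up[ix], seed = seed + 60L)
}
fwrite(rbindlist(coup, idcol = "mark"), "results/coupling_tests.tsv",
       sep = "\t")
message("coupling (up-genes): H3K27ac p = ",
        signif(coup$H3K27ac[comparison == "up", p], 3),
        ", H3K27me3 p = ", signif(coup$H3K27me3[comparison == "up", p], 3))

a2 <- assign_peaks_to_tss(cohort$chip$H3K27ac, de)
r <- expression_chromatin_correlation(de, a2[gene_id %in% de$gene_id],
                                      cohort$chip$H3K27ac, seed = seed + 62L)
message("expression-H3K27ac correlation: median r = ",
        signif(median(r$per_gene$r), 3), ", Wilcoxon p = ",
        signif(r$wilcoxon_p, 3))

ase <- allele_specific_expression(cohort$ase)
fwrite(ase, "results/allele_specific_expression.tsv", sep = "\t")
ct <- bin_pair_signal_correlation(cohort$chip$CTCF, bins)
fwrite(ct, "results/ctcf_bin_correlation.tsv", sep = "\t")
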