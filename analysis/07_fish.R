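#!/usr/bin/env Rscript
# 3D FISH inter-probe distances: nested ANOVA
# (Distance ~ Deletion + Gender + Deletion/Subject, Subject random),
# distances normalized by the product of the nuclear radii.

suppressMessages({library(cnvhic); library(data.table)})
cohort <- readRDS("scratch/cohort.rds")
res <- fish_nested_anova(cohort$fish)
fwrite(res, "results/fish_anova.tsv", sep = "\t")
message("FISH deletion effect: ", signif(res$estimate[1], 3),
        " (normalized distance), F = ", signif(res$F[1], 4),
        ", p = ", signif(res$p[1], 3))
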