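#!/usr/bin/env Rscript
# Differential inter-chromosomal contacts between deletion and control
# groups (two-sided Welch t at p < 1e-4 on depth-scaled values, including
# only cells with a raw pair in every sample), enrichment of significant
# contacts among the top-5% strongest, and label-permutation controls.

suppressMessages({library(cnvhic); library(data.table)})
seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
cohort <- readRDS("scratch/cohort.rds")
mm <- readRDS("scratch/matrices.rds")
labels <- unname(cohort$statuses)

res <- differential_trans_contacts(mm$mats, labels)
fwrite(res, "results/differential_trans.tsv", sep = "\t")
s <- attr(res, "summary")
enr <- strongest_contact_enrichment(res)
message(s$n_significant, " significant trans contacts of ", s$n_tested,
        " tested; ", enr$n_overlap, " of them in the top-5% strongest ",
        "(Fisher p = ", signif(enr$p, 3), ")")

swaps <- label_swap_analysis(mm$mats, labels, "swap10", seed = seed + 40L)
wctrl <- label_swap_analysis(mm$mats, labels, "within_ctrl3", seed = seed + 41L)
wdel <- label_swap_analysis(mm$mats, labels, "within_del3", seed = seed + 42L)
perm <- rbind(cbind(scheme = "swap10", swaps),
              cbind(scheme = "within_ctrl3", wctrl),
              cbind(scheme = "within_del3", wdel))
fwrite(perm, "results/label_permutations.tsv", sep = "\t")
message("max significant count over label swaps: ", max(swaps$n_significant),
        " (true labels: ", s$n_significant, ")")
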