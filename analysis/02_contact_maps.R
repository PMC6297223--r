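#!/usr/bin/env Rscript
# Build depth-scaled 500-kbp contact matrices per sample, average them per
# group, and contrast deletion vs control: genome-wide fold-change maps and
# the 1-Mbp partner-window ranking anchored at the distal flank.

suppressMessages({library(cnvhic); library(data.table)})
cohort <- readRDS("scratch/cohort.rds")
cfg <- cohort$config
bins <- make_bins(cfg$genome, 5e5)

mats <- lapply(names(cohort$samples), function(sid) {
  flt <- filter_pairs(cohort$samples[[sid]]$pairs, cfg$genome,
                      cfg$library_fragment_length, "standard")
  depth_normalize(bin_pairs_to_matrix(flt, bins, sid), cfg$depth_target)
})
names(mats) <- names(cohort$samples)
saveRDS(list(bins = bins, mats = mats), "scratch/matrices.rds")

del_mean <- combine_group(mats[cohort$statuses == "del"])
ctrl_mean <- combine_group(mats[cohort$statuses == "ctrl"])
for (mode in c("log2_ratio", "relative_log2")) {
  fm <- fold_change_map(del_mean, ctrl_mean, mode)
  fwrite(fm, paste0("results/fold_change_", mode, ".tsv"), sep = "\t")
}
del <- cfg$genome$deletions[1]
rk <- cis_window_fold_change_ranking(del_mean, ctrl_mean,
                                     list(del$chrom, del$end, del$end + 5e5),
                                     model = cfg$genome)
fwrite(rk, "results/cis_window_ranking.tsv", sep = "\t")
top <- rk[overlaps_deletion == FALSE][1:3]
message("strongest non-deletion partners of the distal flank window: ",
        paste(sprintf("%.0f-%.0f Mbp (fc %.2f)", top$partner_start / 1e6,
                      top$partner_end / 1e6, top$fold_change),
              collapse = "; "))
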