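#!/usr/bin/env Rscript
# A/B compartments (500 kbp, leading eigenvector of the contact
# correlation matrix) on the control group mean, and topological domains
# (40 kbp, directionality index) per homolog of the capture patient.

suppressMessages({library(cnvhic); library(data.table)})
cohort <- readRDS("scratch/cohort.rds")
mm <- readRDS("scratch/matrices.rds")
cfg <- cohort$config

ctrl_mean <- combine_group(mm$mats[cohort$statuses == "ctrl"])
oe <- observed_over_expected(ctrl_mean, "chr22s")
gd <- gene_density_track(cohort$expression, mm$bins, "chr22s")
comp <- compartment_pc1(oe, gd)
fwrite(comp, "results/compartments.tsv", sep = "\t")
message("compartments: ", sum(comp$label == "A", na.rm = TRUE), " A bins, ",
        sum(comp$label == "B", na.rm = TRUE), " B bins")

pt <- readRDS("scratch/patient.rds")
bins40 <- make_bins(pt$config$genome, pt$config$sim_resolution)
hset <- build_haplotype_matrix(pt$hp, bins40)
for (h in c("H1", "H2")) {
  di <- directionality_index(hset$mean[[h]], "chr22s")
  doms <- call_domains(di, bins40)
  fwrite(di, paste0("results/di_", h, ".tsv"), sep = "\t")
  fwrite(doms, paste0("results/domains_", h, ".tsv"), sep = "\t")
  message(h, ": ", nrow(doms), " domains called")
}
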