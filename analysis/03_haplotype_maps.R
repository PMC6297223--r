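#!/usr/bin/env Rscript
# Homolog-resolved contact maps of a capture-style patient: assign reads
# to haplotypes through phased SNVs, equalize SNV density across the
# deletion, build per-homolog matrices and the deleted-minus-intact
# difference map, and scan for phasing switches.

suppressMessages({library(cnvhic); library(data.table)})
seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
gm <- genome_model(c(chr22s = 50e6),
                   deletions = data.frame(chrom = "chr22s", start = 18.5e6,
                                          end = 21.5e6, haplotype = "H1"))
cfg <- cohort_config(seed = seed + 11L, genome = gm, cis_scale = 150,
                     hotspots = data.frame())
set.seed(cfg$seed)
pairs <- simulate_sample_pairs(cfg, "del", "patient1")
variants <- simulate_phased_snvs(cfg)
tags <- tag_reads_with_alleles(pairs, variants, cfg$read_length)
hp <- assign_pairs_haplotype(
  filter_pairs(pairs, gm, cfg$library_fragment_length, "haplotype"),
  tags, variants)
message("assigned pairs: ", sum(hp$pair_hap != "discard"), " of ", nrow(hp),
        "; discards: ", paste(names(attr(hp, "discard_reasons")),
                              attr(hp, "discard_reasons"), collapse = ", "))

eq <- equalize_snv_density(variants, gm, list("chr22s", 18.5e6, 21.5e6),
                           seed = seed + 12L)
message("SNV-density equalization: expected ", eq$expected,
        " positions per sampling replicate")
bins <- make_bins(gm, 2.5e5)
hset <- build_haplotype_matrix(hp, bins, eq, cfg$read_length)
write_matrix(hset$mean$H1, "results/homolog_H1_bins.tsv",
             "results/homolog_H1_coo.tsv")
write_matrix(hset$mean$H2, "results/homolog_H2_bins.tsv",
             "results/homolog_H2_coo.tsv")
dmap <- haplotype_difference_map(hset$mean$H1, hset$mean$H2)
fwrite(dmap, "results/homolog_difference_map.tsv", sep = "\t")
sw <- detect_phasing_switches(hp, gm)
fwrite(sw, "results/phasing_switches.tsv", sep = "\t")
message("difference map written; ", nrow(sw), " candidate phasing switch(es)")
saveRDS(list(config = cfg, hp = hp[pair_hap %in% c("H1", "H2")]),
        "scratch/patient.rds")
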