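# End-to-end driver: simulate a cohort and run every analysis stage,
# writing plain-text tables. Each stage is also callable on its own; this
# function fixes the order and the resolutions.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort, builds depth-scaled 500-kbp contact matrices and
#' group fold-change maps, ranks anchored cis windows, produces
#' per-homolog maps with SNV-density equalization and their difference
#' map, calls compartments (500 kbp) and domains (40 kbp), tests trans
#' contacts with permutation controls, and runs the ChIP/RNA/ASE/FISH
#' integration statistics. All randomness derives from `config$seed`.
#'
#' @param config a `cohort_config`.
#' @param out_dir optional directory; when given, result tables are written
#'   as TSV (deterministic content for a fixed seed).
#' @param resolution matrix resolution for the group analyses (bp).
#' @param tad_resolution resolution for domain calling (bp).
#' @param n_perm permutations for the coupling tests.
#' @param swap_replicates run the label-swap controls (slowest stage).
#' @return list of all stage results.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         resolution = 5e5, tad_resolution = NULL,
                         n_perm = 9999, swap_replicates = TRUE) {
  if (is.null(tad_resolution)) tad_resolution <- config$sim_resolution
  cohort <- simulate_cohort(config)
  model <- config$genome
  bins <- make_bins(model, resolution)
  statuses <- cohort$statuses

  # --- contact matrices and fold-change maps -------------------------------
  mats <- list()
  for (sid in names(cohort$samples)) {
    flt <- filter_pairs(cohort$samples[[sid]]$pairs, model,
                        config$library_fragment_length, mode = "standard")
    mats[[sid]] <- depth_normalize(bin_pairs_to_matrix(flt, bins, sid),
                                   config$depth_target)
  }
  del_mean <- combine_group(mats[statuses == "del"])
  ctrl_mean <- combine_group(mats[statuses == "ctrl"])
  fc_rel <- fold_change_map(del_mean, ctrl_mean, "relative_log2")
  fc_log2 <- fold_change_map(del_mean, ctrl_mean, "log2_ratio")
  del <- model$deletions[1]
  anchor <- list("chr22s", del$end, del$end + 5e5)
  cis_rank <- cis_window_fold_change_ranking(del_mean, ctrl_mean, anchor,
                                             model = model)

  # --- haplotype-specific maps on the first deletion sample ----------------
  del_sid <- names(statuses)[statuses == "del"][1]
  smp <- cohort$samples[[del_sid]]
  hpairs <- filter_pairs(smp$pairs, model, config$library_fragment_length,
                         mode = "haplotype")
  hpairs <- assign_pairs_haplotype(hpairs, smp$tags, smp$variants)
  eq <- equalize_snv_density(smp$variants, model,
                             list(del$chrom, del$start, del$end),
                             n_samplings = 10, seed = config$seed + 101)
  hset <- build_haplotype_matrix(hpairs, bins, eq, config$read_length)
  hdiff <- haplotype_difference_map(hset$mean$H1, hset$mean$H2)
  switches <- detect_phasing_switches(hpairs, model)

  # --- architecture --------------------------------------------------------
  ctrl_cis <- ctrl_mean
  oe <- observed_over_expected(ctrl_cis, "chr22s")
  gd <- gene_density_track(cohort$expression, bins, "chr22s")
  compartments <- compartment_pc1(oe, gd)
  tbins <- make_bins(model, tad_resolution)
  ctrl_sid <- names(statuses)[statuses == "ctrl"][1]
  tmat <- bin_pairs_to_matrix(
    filter_pairs(cohort$samples[[ctrl_sid]]$pairs, model,
                 config$library_fragment_length, "standard"), tbins)
  di <- directionality_index(tmat, "chr22s")
  domains <- call_domains(di, tbins)

  # --- differential trans contacts -----------------------------------------
  diff_res <- differential_trans_contacts(mats, statuses)
  enrich <- strongest_contact_enrichment(diff_res)
  swaps <- NULL
  if (swap_replicates)
    swaps <- label_swap_analysis(mats, statuses, "swap10",
                                 seed = config$seed + 202)

  # --- integration ----------------------------------------------------------
  de <- simple_de_standin(cohort$expression)
  chip_z <- lapply(cohort$chip, zscore_differential_sites)
  de_enrich <- binned_enrichment(
    de[, .(chrom, pos = tss, significant)], bins)
  assign_ac <- assign_peaks_to_tss(cohort$chip$H3K27ac, de)
  assign_me <- assign_peaks_to_tss(cohort$chip$H3K27me3, de)
  zs_ac <- stats::setNames(chip_z$H3K27ac$zscore, chip_z$H3K27ac$site_id)
  zs_me <- stats::setNames(chip_z$H3K27me3$zscore, chip_z$H3K27me3$site_id)
  ga <- assign_ac[assign_ac$gene_id %in% de$gene_id]
  gm <- assign_me[assign_me$gene_id %in% de$gene_id]
  de_ix <- match(ga$gene_id, de$gene_id)
  coupling_ac <- four_group_coupling_test(
    zs_ac[ga$site_id], de$significant[de_ix], de$up[de_ix],
    n_perm = n_perm, seed = config$seed + 303)
  de_ix2 <- match(gm$gene_id, de$gene_id)
  coupling_me <- four_group_coupling_test(
    zs_me[gm$site_id], de$significant[de_ix2], de$up[de_ix2],
    n_perm = n_perm, seed = config$seed + 304)
  exprcorr <- expression_chromatin_correlation(de, ga, cohort$chip$H3K27ac,
                                               seed = config$seed + 405)
  ase <- allele_specific_expression(cohort$ase)
  ctcf_corr <- bin_pair_signal_correlation(cohort$chip$CTCF, bins)
  fish <- fish_nested_anova(cohort$fish)

  res <- list(config = config, cohort = cohort, matrices = mats,
              del_mean = del_mean, ctrl_mean = ctrl_mean,
              fc_relative = fc_rel, fc_log2 = fc_log2, cis_rank = cis_rank,
              haplotype = list(pairs = hpairs, equalization = eq, set = hset,
                               diff = hdiff, switches = switches),
              compartments = compartments, di = di, domains = domains,
              differential = diff_res, enrichment = enrich, swaps = swaps,
              de = de, chip_z = chip_z, de_enrich = de_enrich,
              coupling = list(H3K27ac = coupling_ac, H3K27me3 = coupling_me),
              exprcorr = exprcorr, ase = ase, ctcf_corr = ctcf_corr,
              fish = fish)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, nm) data.table::fwrite(x, file.path(out_dir, nm),
                                           sep = "\t")
  fw(res$fc_log2, "fold_change_log2.tsv")
  fw(res$fc_relative, "fold_change_relative.tsv")
  fw(res$cis_rank, "cis_window_ranking.tsv")
  fw(res$haplotype$diff, "haplotype_difference_map.tsv")
  fw(res$compartments, "compartments.tsv")
  fw(res$di, "directionality_index.tsv")
  fw(res$domains, "domains.tsv")
  fw(res$differential, "differential_trans.tsv")
  if (!is.null(res$swaps)) fw(res$swaps, "label_swaps.tsv")
  fw(res$de[, .(gene_id, chrom, tss, log2fc, p, fdr_p, significant)],
     "differential_expression.tsv")
  fw(res$de_enrich, "de_binned_enrichment.tsv")
  fw(data.table::rbindlist(res$coupling, idcol = "mark"), "coupling_tests.tsv")
  fw(res$ase[, .(sample_id, chrom, pos, coverage, alt_freq, p0, p)],
     "allele_specific_expression.tsv")
  fw(res$fish, "fish_anova.tsv")
  enr <- res$enrichment
  data.table::fwrite(data.table::data.table(
    n_significant = enr$n_significant, n_top = enr$n_top,
    n_overlap = enr$n_overlap, fisher_p = enr$p),
    file.path(out_dir, "trans_enrichment.tsv"), sep = "\t")
  invisible(out_dir)
}
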