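# Synthetic diploid cohort generator. Every downstream stage of the
# pipeline is exercised on data from this module, with ground truth
# recorded so that parameter recovery and calibration are testable.
#
# The contact model: within a haplotype, the expected count between bins i
# and j at separation s (in bins, on that haplotype's own frame) is
#   lambda = C * max(s,1)^-alpha * comp(i,j) * tad(i,j) * hotspot(i,j)
# with comp = kappa if both bins share a compartment label (else 1/kappa)
# and tad = tau if both bins fall in the same domain (else 1). Trans cells
# have constant rate lambda_t times any hotspot multiplier. Counts are
# Poisson. The deleted homolog uses its own (shorter) coordinate frame, so
# the increased contact between deletion-flanking regions is an emergent
# consequence of the geometry, not an injected effect.

#' Default cohort configuration
#'
#' Returns the full parameter set of the synthetic diploid cohort: a 50-Mbp
#' chromosome emulating 22q with a heterozygous 3-Mbp deletion at
#' 18.5--21.5 Mbp on haplotype H1 of the deletion samples, plus two 8-Mbp
#' decoy chromosomes for trans-contact analyses; 5 deletion and 6 control
#' cell lines.
#'
#' @param seed integer seed; fixed seeds reproduce byte-identical cohorts.
#' @param ... overrides for any config element.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1, ...) {
  genome <- genome_model(
    c(chr22s = 50e6, decoyA = 8e6, decoyB = 8e6),
    deletions = data.frame(chrom = "chr22s", start = 18.5e6, end = 21.5e6,
                           haplotype = "H1"))
  cfg <- list(
    seed = as.integer(seed),
    n_del = 5L, n_ctrl = 6L,
    genome = genome,
    sim_resolution = 4e4,
    decay_exponent = 1.0,        # alpha
    cis_scale = 15,              # C: expected count at 1-bin separation
    trans_rate = 0.06,           # lambda_t per sim-bin pair per haplotype
    compartment_strength = 2,    # kappa >= 1
    tad_strength = 3,            # tau >= 1
    compartment_block = 2.5e6,   # alternating A/B block width, bp
    tad_size = 1.6e6,            # domain width, bp
    snv_density = 1e-3,          # phased het SNVs per bp
    read_length = 101L,
    library_fragment_length = 500,
    # injected contact rewiring: `baseline` elevates the cell in every
    # sample (a constitutively strong contact, e.g. colocalized
    # territories), `multiplier` applies on top of it in deletion samples
    # only. The trans hotspot feeds the differential-trans analyses (the
    # strongest trans contacts are where differential signal is detectable,
    # as the inclusion filter and t test imply), the cis hotspot the
    # anchored window ranking. Both are synthetic constructs.
    hotspots = data.frame(
      chrom1 = c("chr22s", "chr22s"), start1 = c(30e6, 21.5e6),
      end1 = c(30.5e6, 22e6),
      chrom2 = c("decoyA", "chr22s"), start2 = c(3e6, 45e6),
      end2 = c(3.5e6, 45.5e6),
      baseline = c(4, 1),
      multiplier = c(3, 2.5)),
    # ChIP model
    n_peaks_background = c(H3K27ac = 800, H3K27me3 = 600, CTCF = 900),
    chip_sigma = 0.4,            # log2 sd of per-sample peak noise
    flank_regions = data.frame(chrom = "chr22s",
                               start = c(17e6, 21.5e6), end = c(18.5e6, 23e6)),
    flank_effect = 0.8,          # delta: -delta H3K27ac / +delta H3K27me3
    ctcf_corr_windows = data.frame(chrom = "chr22s",
                                   start = c(22e6, 45e6), end = c(22.5e6, 45.5e6)),
    ctcf_corr_sd = 0.6,
    # expression model
    n_genes = 1200L, expr_sigma = 0.25, expr_base_mean = 4, expr_base_sd = 1.5,
    low_expr_fraction = 0.05, de_fraction = 0.08,
    de_effects = c(0.8, 1.2, 1.5),
    coupled_fraction = 0.6, coupling = 0.7, latent_sd = 0.25,
    # allele-specific expression
    ase_n_snvs = 2000L, ase_mean_coverage = 30,
    # FISH model (normalized-distance scale)
    fish_cells_range = c(16L, 33L), fish_grand_mean = 1.0,
    fish_deletion_effect = -0.2, fish_gender_effect = 0.05,
    fish_sd_subject = 0.07, fish_sd_resid = 0.3,
    depth_target = 1e7)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field: ", paste(bad, collapse = ","))
    cfg[names(over)] <- over
  }
  stopifnot(cfg$decay_exponent > 0, cfg$cis_scale >= 0, cfg$trans_rate >= 0,
            cfg$compartment_strength >= 1, cfg$tad_strength >= 1)
  class(cfg) <- "cohort_config"
  cfg
}

#' Compartment label of reference positions (ground truth)
#' @param config a `cohort_config`.
#' @param chrom chromosome name (unused in the default alternating layout,
#'   kept for signature stability).
#' @param pos reference positions, bp.
#' @return character vector of `"A"`/`"B"`.
#' @export
true_compartment <- function(config, chrom, pos) {
  ifelse((pos %/% config$compartment_block) %% 2 == 0, "A", "B")
}

#' Domain index of reference positions (ground truth)
#' @inheritParams true_compartment
#' @export
true_tad_id <- function(config, chrom, pos) {
  as.integer(pos %/% config$tad_size)
}

#' True domain boundaries of a chromosome, bp
#' @inheritParams true_compartment
#' @export
true_tad_boundaries <- function(config, chrom) {
  L <- chrom_length(config$genome, chrom)
  b <- seq(config$tad_size, L - 1, by = config$tad_size)
  b[b > 0 & b < L]
}

# per-haplotype bin geometry for one chromosome of one sample:
# bin starts/widths on the haplotype frame plus reference-frame midpoints
hap_bin_geometry <- function(config, chrom, deleted) {
  res <- config$sim_resolution
  model <- config$genome
  hl <- if (deleted) haplotype_chrom_length(model, "H1", chrom)
        else chrom_length(model, chrom)
  n <- as.integer(ceiling(hl / res))
  start <- (seq_len(n) - 1) * res
  width <- pmin(res, hl - start)
  mid <- start + width / 2
  refmid <- if (deleted) map_haplotype_to_reference(model, "H1", chrom, mid)
            else mid
  list(n = n, start = start, width = width, hap_len = hl, refmid = refmid)
}

# expected-count table for cis cells of one chromosome on one haplotype
cis_lambda_table <- function(config, chrom, deleted, del_sample) {
  g <- hap_bin_geometry(config, chrom, deleted)
  n <- g$n
  i <- rep.int(seq_len(n), times = n:1)
  j <- i - 1L + sequence(n:1)
  s <- pmax(j - i, 1L)
  lab <- true_compartment(config, chrom, g$refmid)
  tid <- true_tad_id(config, chrom, g$refmid)
  kappa <- config$compartment_strength; tau <- config$tad_strength
  lam <- config$cis_scale * s^(-config$decay_exponent) *
    ifelse(lab[i] == lab[j], kappa, 1 / kappa) *
    ifelse(tid[i] == tid[j], tau, 1)
  if (nrow(config$hotspots)) {
    h <- config$hotspots
    for (k in seq_len(nrow(h))) {
      if (h$chrom1[k] != chrom || h$chrom2[k] != chrom) next
      in1 <- function(m) m >= h$start1[k] & m < h$end1[k]
      in2 <- function(m) m >= h$start2[k] & m < h$end2[k]
      hit <- (in1(g$refmid[i]) & in2(g$refmid[j])) |
             (in2(g$refmid[i]) & in1(g$refmid[j]))
      f <- hotspot_base(h, k) * (if (del_sample) h$multiplier[k] else 1)
      lam[hit] <- lam[hit] * f
    }
  }
  list(i = i, j = j, lambda = lam, geom = g)
}

trans_lambda_table <- function(config, chrom1, chrom2, deleted, del_sample) {
  g1 <- hap_bin_geometry(config, chrom1, deleted && chrom_has_del(config, chrom1))
  g2 <- hap_bin_geometry(config, chrom2, deleted && chrom_has_del(config, chrom2))
  i <- rep.int(seq_len(g1$n), times = g2$n)
  j <- rep(seq_len(g2$n), each = g1$n)
  lam <- rep(config$trans_rate, length(i))
  if (nrow(config$hotspots)) {
    h <- config$hotspots
    for (k in seq_len(nrow(h))) {
      if (h$chrom1[k] == chrom1 && h$chrom2[k] == chrom2) {
        hit <- g1$refmid[i] >= h$start1[k] & g1$refmid[i] < h$end1[k] &
               g2$refmid[j] >= h$start2[k] & g2$refmid[j] < h$end2[k]
      } else if (h$chrom1[k] == chrom2 && h$chrom2[k] == chrom1) {
        hit <- g2$refmid[j] >= h$start1[k] & g2$refmid[j] < h$end1[k] &
               g1$refmid[i] >= h$start2[k] & g1$refmid[i] < h$end2[k]
      } else next
      f <- hotspot_base(h, k) * (if (del_sample) h$multiplier[k] else 1)
      lam[hit] <- lam[hit] * f
    }
  }
  list(i = i, j = j, lambda = lam, geom1 = g1, geom2 = g2)
}

hotspot_base <- function(h, k) {
  if ("baseline" %in% names(h)) h$baseline[k] else 1
}

chrom_has_del <- function(config, chrom) {
  any(config$genome$deletions$chrom == chrom &
        config$genome$deletions$haplotype == "H1")
}

# draw positions for `cnt` pairs per cell and map to the reference frame
draw_positions <- function(config, chrom, geom, bin_idx, deleted) {
  p <- floor(geom$start[bin_idx] +
               stats::runif(length(bin_idx)) * geom$width[bin_idx])
  if (deleted) p <- map_haplotype_to_reference(config$genome, "H1", chrom, p)
  as.integer(p)
}

#' Simulate the Hi-C read pairs of one sample
#'
#' Draws Poisson bin-pair counts for both haplotypes of every chromosome
#' (the deleted haplotype of a deletion sample uses its shorter frame, so
#' its deletion bins emit nothing) and materializes each count as a read
#' pair at a uniform position within the bin.
#'
#' @param config a `cohort_config`.
#' @param status `"del"` or `"ctrl"`.
#' @param sample_id metadata tag.
#' @return a `pair_table` with an extra `true_hap` column (generative
#'   truth, not an observed quantity).
#' @export
simulate_sample_pairs <- function(config, status = c("ctrl", "del"),
                                  sample_id = NA_character_) {
  status <- match.arg(status)
  model <- config$genome
  chroms <- model$chromosomes$name
  parts <- list()
  for (hap in c("H1", "H2")) {
    deleted_hap <- status == "del" && hap == "H1"
    for (ci in seq_along(chroms)) {
      cn <- chroms[ci]
      del_here <- deleted_hap && chrom_has_del(config, cn)
      lt <- cis_lambda_table(config, cn, del_here, status == "del")
      cnt <- stats::rpois(length(lt$lambda), lt$lambda)
      nz <- cnt > 0L
      if (any(nz)) {
        bi <- rep.int(lt$i[nz], cnt[nz]); bj <- rep.int(lt$j[nz], cnt[nz])
        parts[[length(parts) + 1L]] <- data.table::data.table(
          chrom1 = cn, pos1 = draw_positions(config, cn, lt$geom, bi, del_here),
          chrom2 = cn, pos2 = draw_positions(config, cn, lt$geom, bj, del_here),
          true_hap = hap)
      }
      if (ci < length(chroms)) for (cj in seq.int(ci + 1L, length(chroms))) {
        cn2 <- chroms[cj]
        del2 <- deleted_hap && chrom_has_del(config, cn2)
        tt <- trans_lambda_table(config, cn, cn2, deleted_hap, status == "del")
        cnt <- stats::rpois(length(tt$lambda), tt$lambda)
        nz <- cnt > 0L
        if (any(nz)) {
          bi <- rep.int(tt$i[nz], cnt[nz]); bj <- rep.int(tt$j[nz], cnt[nz])
          parts[[length(parts) + 1L]] <- data.table::data.table(
            chrom1 = cn,
            pos1 = draw_positions(config, cn, tt$geom1, bi, del_here),
            chrom2 = cn2,
            pos2 = draw_positions(config, cn2, tt$geom2, bj, del2),
            true_hap = hap)
        }
      }
    }
  }
  dt <- data.table::rbindlist(parts)
  n <- nrow(dt)
  dt[, read_id := seq_len(n)]
  dt[, strand1 := sample(c("+", "-"), n, replace = TRUE)]
  dt[, strand2 := sample(c("+", "-"), n, replace = TRUE)]
  pt <- pair_table(dt, model)
  data.table::setattr(pt, "sample_id", sample_id)
  pt
}

#' Simulate a directly binned contact matrix (no read materialization)
#'
#' Same generative model as [simulate_sample_pairs()], but emitting Poisson
#' counts straight into a `contact_matrix` at the simulation resolution,
#' on the reference-frame bin scheme. Deleted-haplotype cells are assigned
#' to reference bins by their mapped midpoints. Fast path for architecture
#' analyses on single homologs.
#'
#' @param config a `cohort_config`.
#' @param status `"del"` or `"ctrl"` (controls hotspot injection and the
#'   H1 frame).
#' @param haplotype `"H1"` or `"H2"`.
#' @param chrom optional chromosome restriction (cis only); default all
#'   chromosomes, cis cells only.
#' @export
simulate_bin_matrix <- function(config, status = c("ctrl", "del"),
                                haplotype = c("H1", "H2"), chrom = NULL) {
  status <- match.arg(status); haplotype <- match.arg(haplotype)
  model <- config$genome
  bins <- make_bins(model, config$sim_resolution)
  chroms <- if (is.null(chrom)) model$chromosomes$name else chrom
  deleted_hap <- status == "del" && haplotype == "H1"
  parts <- list()
  for (cn in chroms) {
    del_here <- deleted_hap && chrom_has_del(config, cn)
    lt <- cis_lambda_table(config, cn, del_here, status == "del")
    cnt <- stats::rpois(length(lt$lambda), lt$lambda)
    nz <- which(cnt > 0L)
    if (!length(nz)) next
    # reference-frame bin of each haplotype-frame bin, by mapped midpoint
    refbin <- bin_id_of(bins, rep(cn, lt$geom$n), lt$geom$refmid)
    parts[[length(parts) + 1L]] <- data.table::data.table(
      bin1 = refbin[lt$i[nz]], bin2 = refbin[lt$j[nz]],
      value = as.numeric(cnt[nz]))
  }
  contact_matrix(data.table::rbindlist(parts), bins, "raw",
                 sample_id = paste0(status, "_", haplotype))
}

#' Simulate phased heterozygous SNVs for one individual
#'
#' Positions are uniform at the configured density on the reference frame
#' of every chromosome (SNVs inside the deletion exist on the intact
#' haplotype; reads from the deleted haplotype simply never cover them).
#'
#' @param config a `cohort_config`.
#' @return a phased-variant data.table (see [read_phased_variants()]).
#' @export
simulate_phased_snvs <- function(config) {
  stopifnot(config$snv_density > 0)
  model <- config$genome
  bases <- c("A", "C", "G", "T")
  parts <- lapply(seq_len(nrow(model$chromosomes)), function(i) {
    L <- model$chromosomes$length[i]
    n <- stats::rpois(1, config$snv_density * L)
    pos <- sort(sample.int(L, n)) - 1
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    alt_on_h1 <- stats::runif(n) < 0.5
    data.table::data.table(
      chrom = model$chromosomes$name[i], pos = pos,
      ref_allele = ref, alt_allele = alt,
      hap1_allele = ifelse(alt_on_h1, alt, ref),
      hap2_allele = ifelse(alt_on_h1, ref, alt))
  })
  data.table::rbindlist(parts)
}

#' Tag simulated reads with the SNV alleles they cover
#'
#' Each read end covers `read_length` bp from its position; every phased
#' SNV under the read contributes the allele of the read's true haplotype.
#'
#' @param pairs a `pair_table` with a `true_hap` column.
#' @param variants phased-variant table of the same individual.
#' @param read_length read length, bp.
#' @return data.table of tags (`read_id`, `end`, `chrom`, `pos`, `allele`).
#' @export
tag_reads_with_alleles <- function(pairs, variants, read_length = 101L) {
  stopifnot("true_hap" %in% names(pairs))
  out <- list()
  for (end in 1:2) {
    pcol <- paste0("pos", end); ccol <- paste0("chrom", end)
    for (cn in unique(pairs[[ccol]])) {
      v <- variants[variants$chrom == cn]
      if (nrow(v) == 0L) next
      sel <- which(pairs[[ccol]] == cn)
      pos <- pairs[[pcol]][sel]
      lo <- findInterval(pos - 0.5, v$pos) + 1L
      hi <- findInterval(pos + read_length - 0.5, v$pos)
      cnt <- hi - lo + 1L
      has <- which(cnt > 0L)
      if (!length(has)) next
      idx <- sequence(cnt[has]) + rep.int(lo[has] - 1L, cnt[has])
      rid <- rep.int(pairs$read_id[sel[has]], cnt[has])
      hap <- rep.int(pairs$true_hap[sel[has]], cnt[has])
      out[[length(out) + 1L]] <- data.table::data.table(
        read_id = rid, end = end, chrom = cn, pos = v$pos[idx],
        allele = ifelse(hap == "H1", v$hap1_allele[idx], v$hap2_allele[idx]))
    }
  }
  if (!length(out))
    return(data.table::data.table(read_id = integer(), end = integer(),
                                  chrom = character(), pos = numeric(),
                                  allele = character()))
  data.table::rbindlist(out)
}

# gene/peak layout with all truth effects; shared by ChIP and expression
simulate_feature_layout <- function(config) {
  model <- config$genome
  chroms <- model$chromosomes
  # genes: uniform proposals thinned so A compartments are gene-richer
  n_prop <- config$n_genes * 3L
  ci <- sample.int(nrow(chroms), n_prop, replace = TRUE,
                   prob = chroms$length)
  tss <- floor(stats::runif(n_prop) * chroms$length[ci])
  w <- ifelse(true_compartment(config, chroms$name[ci], tss) == "A", 1, 0.45)
  keep <- sample.int(n_prop, config$n_genes, prob = w)
  genes <- data.table::data.table(
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    chrom = chroms$name[ci[keep]], tss = tss[keep],
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE))
  data.table::setorder(genes, chrom, tss)
  genes[, gene_id := sprintf("gene%04d", seq_len(.N))]
  genes[, base_log2 := stats::rnorm(.N, config$expr_base_mean, config$expr_base_sd)]
  n_low <- round(config$low_expr_fraction * nrow(genes))
  low <- sample.int(nrow(genes), n_low)
  genes[low, base_log2 := log2(0.1)]
  # truth effects (log2, applied in deletion samples)
  dels <- model$deletions
  genes[, in_deletion := FALSE]
  for (k in seq_len(nrow(dels)))
    genes[chrom == dels$chrom[k] & tss >= dels$start[k] & tss < dels$end[k],
          in_deletion := TRUE]
  genes[, effect_log2 := ifelse(in_deletion, -1, 0)]
  cand <- which(!genes$in_deletion & !(seq_len(nrow(genes)) %in% low))
  n_de <- round(config$de_fraction * nrow(genes))
  de <- sample(cand, n_de)
  genes[de, effect_log2 := sample(config$de_effects, n_de, replace = TRUE) *
              sample(c(-1, 1), n_de, replace = TRUE)]
  genes[, coupled := FALSE]
  genes[sample.int(nrow(genes), round(config$coupled_fraction * nrow(genes))),
        coupled := TRUE]

  # peaks: TSS-linked peaks for coupled genes plus uniform background
  mk_bg <- function(mark, n, width) {
    ci <- sample.int(nrow(chroms), n, replace = TRUE, prob = chroms$length)
    st <- floor(stats::runif(n) * (chroms$length[ci] - width))
    data.table::data.table(chrom = chroms$name[ci], start = st,
                           end = st + width, mark = mark,
                           gene_id = NA_character_)
  }
  cg <- genes[coupled == TRUE]
  pk_ac <- data.table::data.table(
    chrom = cg$chrom,
    start = pmax(0, cg$tss + round(stats::runif(nrow(cg), -800, 500)) - 150),
    mark = "H3K27ac", gene_id = cg$gene_id)
  pk_ac[, end := start + 600]
  pk_me <- data.table::data.table(
    chrom = cg$chrom,
    start = pmax(0, cg$tss + round(stats::runif(nrow(cg), -4500, 3500)) - 500),
    mark = "H3K27me3", gene_id = cg$gene_id)
  pk_me[, end := start + 1500]
  ctcf_w <- config$ctcf_corr_windows
  pk_ctcf_w <- data.table::rbindlist(lapply(seq_len(nrow(ctcf_w)), function(k) {
    st <- floor(seq(ctcf_w$start[k], ctcf_w$end[k] - 1200, length.out = 5))
    data.table::data.table(chrom = ctcf_w$chrom[k], start = st, end = st + 800,
                           mark = "CTCF", gene_id = NA_character_)
  }))
  peaks <- data.table::rbindlist(list(
    pk_ac[, .(chrom, start, end, mark, gene_id)],
    pk_me[, .(chrom, start, end, mark, gene_id)],
    mk_bg("H3K27ac", config$n_peaks_background[["H3K27ac"]], 600),
    mk_bg("H3K27me3", config$n_peaks_background[["H3K27me3"]], 1500),
    mk_bg("CTCF", config$n_peaks_background[["CTCF"]], 800),
    pk_ctcf_w))
  data.table::setorder(peaks, mark, chrom, start)
  peaks[, site_id := sprintf("%s_%05d", mark, seq_len(.N)), by = mark]
  peaks[, base_log2 := stats::rnorm(.N, 6, 1)]
  peaks[, in_deletion := FALSE]
  for (k in seq_len(nrow(dels)))
    peaks[chrom == dels$chrom[k] &
            (start + end) / 2 >= dels$start[k] & (start + end) / 2 < dels$end[k],
          in_deletion := TRUE]
  peaks[, in_flank := FALSE]
  fl <- config$flank_regions
  for (k in seq_len(nrow(fl)))
    peaks[chrom == fl$chrom[k] &
            (start + end) / 2 >= fl$start[k] & (start + end) / 2 < fl$end[k],
          in_flank := TRUE]
  # truth log2 effect in deletion samples, reciprocal in the flanks
  peaks[, effect_log2 := ifelse(in_deletion, -1, 0)]
  peaks[in_flank & !in_deletion & mark == "H3K27ac",
        effect_log2 := effect_log2 - config$flank_effect]
  peaks[in_flank & !in_deletion & mark == "H3K27me3",
        effect_log2 := effect_log2 + config$flank_effect]
  # expression coupling: the TSS peak of a DE gene moves with it
  ge <- stats::setNames(genes$effect_log2, genes$gene_id)
  peaks[!is.na(gene_id) & mark == "H3K27ac" & !in_deletion & !in_flank,
        effect_log2 := effect_log2 + config$coupling * ge[gene_id]]
  peaks[!is.na(gene_id) & mark == "H3K27me3" & !in_deletion & !in_flank,
        effect_log2 := effect_log2 - config$coupling * ge[gene_id]]
  # CTCF correlated-window membership
  peaks[, corr_window := 0L]
  for (k in seq_len(nrow(ctcf_w)))
    peaks[mark == "CTCF" & chrom == ctcf_w$chrom[k] &
            (start + end) / 2 >= ctcf_w$start[k] &
            (start + end) / 2 < ctcf_w$end[k], corr_window := k]
  list(genes = genes, peaks = peaks)
}

sample_frame <- function(config) {
  data.table::data.table(
    sample_id = c(sprintf("del%02d", seq_len(config$n_del)),
                  sprintf("ctrl%02d", seq_len(config$n_ctrl))),
    status = c(rep("del", config$n_del), rep("ctrl", config$n_ctrl)))
}

#' Simulate per-mark ChIP signal tables
#'
#' Per-peak per-sample normalized counts are log-normal around a per-peak
#' baseline; peaks inside the deletion lose one log2 unit in deletion
#' samples (heterozygous halving), flank peaks move reciprocally
#' (H3K27ac down, H3K27me3 up), and TSS-linked peaks of differentially
#' expressed genes move with their gene.
#'
#' @param config a `cohort_config`.
#' @param layout feature layout from the cohort simulation.
#' @param latent per-gene-per-sample latent matrix coupling expression and
#'   H3K27ac (rows = genes, columns = samples), or `NULL`.
#' @return named list of wide signal tables (one per mark) with a `groups`
#'   attribute mapping sample to status and truth columns retained.
#' @export
simulate_chip_tables <- function(config, layout, latent = NULL) {
  stopifnot(config$chip_sigma > 0)
  sm <- sample_frame(config)
  out <- list()
  for (mk in unique(layout$peaks$mark)) {
    p <- layout$peaks[layout$peaks$mark == mk]
    n <- nrow(p)
    # one shared per-sample factor drives all correlated CTCF windows, so
    # their bin means co-vary across the cohort
    ctcf_f <- stats::rnorm(nrow(sm), 0, config$ctcf_corr_sd)
    vals <- matrix(0, n, nrow(sm))
    for (s in seq_len(nrow(sm))) {
      mu <- p$base_log2 + p$effect_log2 * (sm$status[s] == "del")
      if (mk == "CTCF") mu[p$corr_window > 0] <- mu[p$corr_window > 0] +
          ctcf_f[s]
      if (mk == "H3K27ac" && !is.null(latent)) {
        gi <- match(p$gene_id, rownames(latent))
        mu[!is.na(gi)] <- mu[!is.na(gi)] + latent[gi[!is.na(gi)], s]
      }
      vals[, s] <- 2^(mu + stats::rnorm(n, 0, config$chip_sigma))
    }
    tab <- data.table::data.table(site_id = p$site_id, chrom = p$chrom,
                                  start = p$start, end = p$end, mark = mk,
                                  gene_id = p$gene_id,
                                  truth_effect_log2 = p$effect_log2,
                                  in_deletion = p$in_deletion,
                                  in_flank = p$in_flank)
    for (s in seq_len(nrow(sm))) tab[, (sm$sample_id[s]) := vals[, s]]
    data.table::setattr(tab, "groups",
                        stats::setNames(sm$status, sm$sample_id))
    out[[mk]] <- tab
  }
  out
}

#' Simulate the gene expression (FPKM) table
#'
#' Deletion genes are halved in deletion samples; a configured fraction of
#' genome-wide genes carries true differential effects; a low-expression
#' subset exercises the FPKM filter.
#'
#' @inheritParams simulate_chip_tables
#' @return wide expression table with a `groups` attribute, plus the latent
#'   matrix in attribute `latent` for coupling with H3K27ac.
#' @export
simulate_expression_table <- function(config, layout) {
  sm <- sample_frame(config)
  g <- layout$genes
  latent <- matrix(stats::rnorm(nrow(g) * nrow(sm), 0, config$latent_sd),
                   nrow = nrow(g), dimnames = list(g$gene_id, sm$sample_id))
  tab <- data.table::data.table(gene_id = g$gene_id, chrom = g$chrom,
                                tss = g$tss, strand = g$strand,
                                truth_effect_log2 = g$effect_log2,
                                in_deletion = g$in_deletion,
                                coupled = g$coupled)
  for (s in seq_len(nrow(sm))) {
    mu <- g$base_log2 + g$effect_log2 * (sm$status[s] == "del") + latent[, s]
    tab[, (sm$sample_id[s]) := 2^(mu + stats::rnorm(nrow(g), 0, config$expr_sigma))]
  }
  data.table::setattr(tab, "groups", stats::setNames(sm$status, sm$sample_id))
  data.table::setattr(tab, "latent", latent)
  tab
}

#' Simulate allele-specific RNA read counts at phased SNVs
#'
#' Outside the deletion, alternative-allele counts are binomial at 0.5; at
#' SNVs inside the deletion of a deletion sample all RNA comes from the
#' intact haplotype, so counts are monoallelic.
#'
#' @param config a `cohort_config`.
#' @param variants_by_sample named list of phased-variant tables.
#' @param statuses named status vector (sample -> `"del"`/`"ctrl"`).
#' @return data.table (`sample_id`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`, `in_deletion`).
#' @export
simulate_ase_counts <- function(config, variants_by_sample, statuses) {
  dels <- config$genome$deletions
  out <- list()
  for (sid in names(variants_by_sample)) {
    v <- variants_by_sample[[sid]]
    take <- sort(sample.int(nrow(v), min(config$ase_n_snvs, nrow(v))))
    v <- v[take]
    cov <- stats::rpois(nrow(v), config$ase_mean_coverage)
    in_del <- rep(FALSE, nrow(v))
    for (k in seq_len(nrow(dels)))
      in_del <- in_del | (v$chrom == dels$chrom[k] & v$pos >= dels$start[k] &
                            v$pos < dels$end[k])
    mono <- in_del & statuses[[sid]] == "del"
    alt <- integer(nrow(v))
    alt[!mono] <- stats::rbinom(sum(!mono), cov[!mono], 0.5)
    # expression only from the intact haplotype (H2)
    alt[mono] <- ifelse(v$hap2_allele[mono] == v$alt_allele[mono],
                        cov[mono], 0L)
    out[[sid]] <- data.table::data.table(
      sample_id = sid, chrom = v$chrom, pos = v$pos,
      ref_count = cov - alt, alt_count = alt, in_deletion = in_del)
  }
  data.table::rbindlist(out)
}

#' Simulate 3D FISH inter-probe distances
#'
#' Normalized-scale distance = grand mean + deletion effect + gender effect
#' + subject random intercept + residual; the emitted raw distance is the
#' normalized value times the product of the two nuclear radii, so that
#' normalization by `r_short * r_long` recovers the model scale exactly.
#'
#' @param config a `cohort_config`.
#' @return data.table, one row per imaged cell.
#' @export
simulate_fish_measurements <- function(config) {
  sm <- sample_frame(config)
  sm[, gender := rep(c("M", "F"), length.out = .N), by = status]
  out <- list()
  cell_counts <- seq(config$fish_cells_range[1], config$fish_cells_range[2])
  for (s in seq_len(nrow(sm))) {
    n <- cell_counts[sample.int(length(cell_counts), 1)]
    subj_eff <- stats::rnorm(1, 0, config$fish_sd_subject)
    d <- config$fish_grand_mean +
      config$fish_deletion_effect * (sm$status[s] == "del") +
      config$fish_gender_effect * (sm$gender[s] == "M") +
      subj_eff + stats::rnorm(n, 0, config$fish_sd_resid)
    r_short <- stats::runif(n, 4, 6); r_long <- stats::runif(n, 6, 8)
    out[[s]] <- data.table::data.table(
      subject = sm$sample_id[s], deletion = sm$status[s] == "del",
      gender = sm$gender[s], cell_id = seq_len(n),
      raw_distance = d * r_short * r_long,
      r_short = r_short, r_long = r_long)
  }
  data.table::rbindlist(out)
}

#' Simulate the full diploid cohort
#'
#' Orchestrates every generator under one seed: per-sample Hi-C read pairs
#' with allele tags and phased SNVs, ChIP signal tables, expression, ASE
#' counts, FISH distances, and the ground-truth set.
#'
#' @param config a `cohort_config`.
#' @param pairs set `FALSE` to skip read-pair simulation (feature tables
#'   only), e.g. for integration-only analyses.
#' @return list with elements `samples` (per-sample list of `pairs`,
#'   `variants`, `tags`), `chip`, `expression`, `ase`, `fish`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), pairs = TRUE) {
  set.seed(config$seed)
  sm <- sample_frame(config)
  samples <- list()
  if (pairs) {
    for (s in seq_len(nrow(sm))) {
      sid <- sm$sample_id[s]
      pp <- simulate_sample_pairs(config, sm$status[s], sid)
      vv <- simulate_phased_snvs(config)
      tt <- tag_reads_with_alleles(pp, vv, config$read_length)
      samples[[sid]] <- list(pairs = pp, variants = vv, tags = tt,
                             status = sm$status[s])
    }
  } else {
    for (s in seq_len(nrow(sm)))
      samples[[sm$sample_id[s]]] <- list(variants = simulate_phased_snvs(config),
                                         status = sm$status[s])
  }
  layout <- simulate_feature_layout(config)
  expression <- simulate_expression_table(config, layout)
  chip <- simulate_chip_tables(config, layout, attr(expression, "latent"))
  statuses <- stats::setNames(sm$status, sm$sample_id)
  ase <- simulate_ase_counts(config,
                             lapply(samples, `[[`, "variants"), statuses)
  fish <- simulate_fish_measurements(config)
  truth <- list(
    tad_boundaries = lapply(stats::setNames(nm = config$genome$chromosomes$name),
                            function(cn) true_tad_boundaries(config, cn)),
    genes = layout$genes, peaks = layout$peaks,
    hotspots = config$hotspots,
    fish_deletion_effect = config$fish_deletion_effect)
  list(samples = samples, statuses = statuses, chip = chip,
       expression = expression, ase = ase, fish = fish, truth = truth,
       config = config)
}
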