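# Haplotype assignment exactness, SNV-density equalization, per-homolog
# maps, the homolog difference map, and phase-switch detection.

test_that("end and pair haplotype calls follow the matching rules", {
  v <- data.table::data.table(chrom = "c", pos = c(10, 20, 30),
                              ref_allele = c("A", "C", "G"),
                              alt_allele = c("G", "T", "A"),
                              hap1_allele = c("A", "T", "G"),
                              hap2_allele = c("G", "C", "A"))
  tags <- data.table::data.table(
    read_id = c(1L, 2L, 2L, 3L, 4L),
    end = 1L, chrom = "c",
    pos = c(10, 10, 20, 20, 30),
    allele = c("A", "A", "C", "C", "A"))
  calls <- assign_read_haplotype(tags, v)
  expect_equal(calls$haplotype[calls$read_id == 1], "H1")
  expect_equal(calls$haplotype[calls$read_id == 2], "conflict") # H1 then H2
  expect_equal(calls$haplotype[calls$read_id == 3], "H2")
  expect_equal(calls$haplotype[calls$read_id == 4], "H2")
  expect_error(assign_read_haplotype(
    data.table::data.table(read_id = 1L, end = 1L, chrom = "c", pos = 99,
                           allele = "A"), v), "not present")

  r <- resolve_pair_haplotype(
    c("H1", "H2", "H1", "unknown", "H1", "conflict"),
    c("H1", "unknown", "H2", "unknown", "conflict", "H2"))
  expect_equal(r$haplotype,
               c("H1", "H2", "discard", "discard", "discard", "discard"))
  expect_equal(r$reasons,
               c(conflict = 2L, cross_haplotype = 1L, no_information = 1L))
})

test_that("error-free tags give perfect assignment and no conflicts", {
  hp <- default_hap_pairs()
  informative <- hp[hp$pair_hap %in% c("H1", "H2"), ]
  expect_gt(nrow(informative), 1e5)
  expect_equal(mean(informative$pair_hap == informative$true_hap), 1)
  expect_equal(sum(hp$hap1 == "conflict" | hp$hap2 == "conflict"), 0)
  expect_equal(attr(hp, "discard_reasons")[["cross_haplotype"]], 0L)
})

test_that("assigned fraction rises with SNV density", {
  frac <- vapply(c(2e-4, 1e-3, 4e-3), function(d) {
    cfg <- tiny_config(seed = 5, snv_density = d)
    set.seed(5)
    p <- simulate_sample_pairs(cfg, "ctrl")[1:50000]
    v <- simulate_phased_snvs(cfg)
    hp <- assign_pairs_haplotype(p, tag_reads_with_alleles(p, v), v)
    mean(hp$pair_hap != "discard")
  }, 0)
  expect_true(all(diff(frac) > 0))
})

test_that("equalization expected count matches a brute-force oracle", {
  cfg <- tiny_config(seed = 8)
  set.seed(8)
  v <- simulate_phased_snvs(cfg)
  m <- cfg$genome
  set.seed(9)
  for (k in 1:100) {
    st <- runif(1, 0, 8e6); en <- st + runif(1, 5e5, 1.9e6)
    eq <- equalize_snv_density(v, m, list("chrA", st, en), n_samplings = 2,
                               seed = k)
    # oracle: count outside, density, expected
    vp <- v$pos[v$chrom == "chrA"]
    n_out <- sum(vp < st | vp >= en)
    exp_oracle <- round((en - st) * n_out / (10e6 - (en - st)))
    expect_equal(eq$expected, exp_oracle)
    expect_true(all(lengths(eq$replicates) == eq$expected))
    expect_true(all(eq$replicates[[1]] >= st & eq$replicates[[1]] < en))
    expect_false(any(duplicated(eq$replicates[[1]])))
  }
  # replicate sets differ across seeds, sizes fixed
  e1 <- equalize_snv_density(v, m, list("chrA", 5e6, 7e6), seed = 1)
  e2 <- equalize_snv_density(v, m, list("chrA", 5e6, 7e6), seed = 2)
  expect_false(identical(e1$replicates[[1]], e2$replicates[[1]]))
  expect_equal(lengths(e1$replicates), lengths(e2$replicates))
  # sampled positions look uniform over the region
  pooled <- (unlist(e1$replicates) - 5e6 + 0.5) / 2e6
  expect_gt(suppressWarnings(stats::ks.test(pooled, "punif")$p.value), 0.01)
  expect_error(equalize_snv_density(v, m, list("chrA", 0, 10e6)),
               "whole chromosome")
})

test_that("per-homolog maps are empty in the deletion and balanced in controls", {
  co <- default_cohort()
  cfg <- co$config
  bins <- make_bins(cfg$genome, 5e5)
  hp <- default_hap_pairs()
  del <- cfg$genome$deletions[1]
  eq <- equalize_snv_density(co$samples[[1]]$variants, cfg$genome,
                             list(del$chrom, del$start, del$end), seed = 3)
  hset <- build_haplotype_matrix(hp, bins, eq, cfg$read_length)
  bt <- bins$bins
  del_bins <- bt[bt$chrom == "chr22s" & bt$start >= 18.5e6 &
                   bt$end <= 21.5e6, bin_id]
  h1 <- hset$mean$H1$entries
  expect_equal(sum(h1$value[h1$bin1 %in% del_bins | h1$bin2 %in% del_bins]), 0)
  h2 <- hset$mean$H2$entries
  expect_gt(sum(h2$value[h2$bin1 %in% del_bins | h2$bin2 %in% del_bins]), 0)

  # control sample: the two homologs agree within Poisson noise
  ctrl_sid <- names(co$statuses)[co$statuses == "ctrl"][1]
  smp <- co$samples[[ctrl_sid]]
  cp <- filter_pairs(smp$pairs, cfg$genome, cfg$library_fragment_length,
                     "haplotype")
  cp <- assign_pairs_haplotype(cp, smp$tags, smp$variants)
  cset <- build_haplotype_matrix(cp, bins)
  a <- merge(cset$mean$H1$entries, cset$mean$H2$entries,
             by = c("bin1", "bin2"), all = TRUE)
  a[is.na(a)] <- 0
  z <- (a$value.x - a$value.y) / sqrt(pmax(a$value.x + a$value.y, 1))
  expect_equal(sum(abs(z) > 5), 0)
})

test_that("equalization sampling replicates reproduce the same contact pattern", {
  # capture-depth patient: each sampling replicate's region-contact profile
  # agrees with the consensus of the other nine
  cap <- capture_patient()
  cfg <- cap$config
  bins <- make_bins(cfg$genome, 5e5)
  hset <- build_haplotype_matrix(cap$pairs, bins, cap$equalization,
                                 cfg$read_length)
  bt <- bins$bins
  del_bins <- bt[bt$start >= 18.5e6 & bt$end <= 21.5e6, bin_id]
  profiles <- sapply(hset$replicates, function(r) {
    e <- r$H2$entries
    reg <- e[e$bin1 %in% del_bins | e$bin2 %in% del_bins, ]
    partner <- ifelse(reg$bin1 %in% del_bins, reg$bin2, reg$bin1)
    vapply(bt$bin_id, function(b) sum(reg$value[partner == b]), 0)
  })
  # 1-Mbp partner windows
  pr <- apply(profiles, 2, function(x) tapply(x, (seq_along(x) - 1) %/% 2, sum))
  loo <- vapply(1:10, function(k)
    stats::cor(pr[, k], rowMeans(pr[, -k]), method = "spearman"), 0)
  expect_gte(min(loo), 0.9)
  # the deleted homolog stays empty in the region in every replicate
  for (r in hset$replicates) {
    e <- r$H1$entries
    expect_equal(sum(e$value[e$bin1 %in% del_bins | e$bin2 %in% del_bins]), 0)
  }
})

test_that("homolog difference map shows the flank block only on the deleted homolog", {
  co <- default_cohort()
  cfg <- co$config
  bins <- make_bins(cfg$genome, 2.5e5)
  hp <- default_hap_pairs()
  hset <- build_haplotype_matrix(hp, bins)
  dmap <- haplotype_difference_map(hset$mean$H1, hset$mean$H2)
  bt <- bins$bins
  fp <- bt[bt$chrom == "chr22s" & bt$start >= 17e6 & bt$end <= 18.5e6, bin_id]
  fd <- bt[bt$chrom == "chr22s" & bt$start >= 21.5e6 & bt$end <= 23e6, bin_id]
  blk <- dmap[dmap$bin1 %in% fp & dmap$bin2 %in% fd, ]
  expect_gte(nrow(blk), 30)
  # sign test: flank x flank cells are overwhelmingly positive
  n_pos <- sum(blk$diff > 0); n_eff <- sum(blk$diff != 0)
  expect_lt(stats::binom.test(n_pos, n_eff, 0.5,
                              alternative = "greater")$p.value, 0.01)
  # deletion rows are negative (intact homolog has the contacts)
  del_bins <- bt[bt$chrom == "chr22s" & bt$start >= 18.5e6 &
                   bt$end <= 21.5e6, bin_id]
  dd <- dmap[dmap$bin1 %in% del_bins | dmap$bin2 %in% del_bins, ]
  expect_true(all(dd$diff <= 0))

  # identical homologs give an all-zero map
  z <- haplotype_difference_map(hset$mean$H2, hset$mean$H2)
  expect_true(all(z$diff == 0))

  # intact-vs-intact (control sample) has no flank block
  ctrl_sid <- names(co$statuses)[co$statuses == "ctrl"][1]
  smp <- co$samples[[ctrl_sid]]
  cp <- assign_pairs_haplotype(
    filter_pairs(smp$pairs, cfg$genome, cfg$library_fragment_length,
                 "haplotype"), smp$tags, smp$variants)
  cset <- build_haplotype_matrix(cp, bins)
  cmap <- haplotype_difference_map(cset$mean$H1, cset$mean$H2)
  cblk <- cmap[cmap$bin1 %in% fp & cmap$bin2 %in% fd, ]
  n_pos_c <- sum(cblk$diff > 0); n_eff_c <- sum(cblk$diff != 0)
  expect_gt(stats::binom.test(n_pos_c, n_eff_c, 0.5,
                              alternative = "greater")$p.value, 0.01)
})

test_that("deleted-homolog flank contacts fit the haplotype frame, not the reference", {
  co <- default_cohort()
  cfg <- co$config
  hp <- default_hap_pairs()
  bins <- make_bins(cfg$genome, cfg$sim_resolution)
  hset <- build_haplotype_matrix(hp, bins)
  res <- cfg$sim_resolution
  bt <- bins$bins
  fp <- bt[bt$chrom == "chr22s" & bt$start >= 16e6 & bt$end <= 18.5e6, bin_id]
  fd <- bt[bt$chrom == "chr22s" & bt$start >= 21.5e6 & bt$end <= 24e6, bin_id]
  Lbins <- 3e6 / res
  alpha <- cfg$decay_exponent
  # with the decay exponent known, model selection between the two
  # coordinate frames is by Poisson deviance of the per-separation totals
  # against scale * n_cells * s_eff^-alpha, scale fitted per frame
  all_seps <- as.vector(outer(fp, fd, function(a, b) b - a))
  sep_levels <- sort(unique(all_seps))
  n_cells <- tabulate(factor(all_seps, levels = sep_levels))
  frame_deviance <- function(cm, mapped) {
    e <- cm$entries[cm$entries$bin1 %in% fp & cm$entries$bin2 %in% fd, ]
    y <- vapply(sep_levels, function(s)
      sum(e$value[e$bin2 - e$bin1 == s]), 0)
    s_eff <- sep_levels - if (mapped) Lbins else 0
    ok <- s_eff > 0
    w <- n_cells[ok] * s_eff[ok]^(-alpha)
    mu <- w * sum(y[ok]) / sum(w)
    2 * sum(ifelse(y[ok] > 0, y[ok] * log(y[ok] / mu), 0) - (y[ok] - mu))
  }
  expect_lt(frame_deviance(hset$mean$H1, mapped = TRUE),
            frame_deviance(hset$mean$H1, mapped = FALSE))
  # and the intact homolog fits the reference frame
  expect_lt(frame_deviance(hset$mean$H2, mapped = FALSE),
            frame_deviance(hset$mean$H2, mapped = TRUE))
})

test_that("homolog decay exponent is recovered from assigned pairs", {
  co <- default_cohort()
  cfg <- co$config
  hp <- default_hap_pairs()
  bins <- make_bins(cfg$genome, cfg$sim_resolution)
  hset <- build_haplotype_matrix(hp, bins)
  e2 <- hset$mean$H2$entries
  bt <- bins$bins
  ch <- bt[bt$chrom == "chr22s", bin_id]
  e2 <- e2[e2$bin1 %in% ch & e2$bin2 %in% ch, ]
  sep2 <- e2$bin2 - e2$bin1
  res <- cfg$sim_resolution
  mids <- (seq_len(1250) - 0.5) * res
  lab <- true_compartment(cfg, "chr22s", mids)
  tid <- true_tad_id(cfg, "chr22s", mids)
  rng <- 2:300
  means2 <- vapply(rng, function(s) {
    i <- seq_len(1250 - s)
    fac <- ifelse(lab[i] == lab[i + s], cfg$compartment_strength,
                  1 / cfg$compartment_strength) *
      ifelse(tid[i] == tid[i + s], cfg$tad_strength, 1)
    sum(e2$value[sep2 == s]) / sum(fac)
  }, 0)
  fit <- stats::lm(log(means2) ~ log(rng))
  expect_lt(abs(stats::coef(fit)[2] + cfg$decay_exponent), 0.15)
})

test_that("phase-switch detector flags a constructed switch and stays quiet otherwise", {
  cfg <- tiny_config(seed = 13, snv_density = 2e-3)
  set.seed(13)
  p <- simulate_sample_pairs(cfg, "ctrl")
  v <- simulate_phased_snvs(cfg)
  hp <- assign_pairs_haplotype(p, tag_reads_with_alleles(p, v), v)
  clean <- detect_phasing_switches(hp, cfg$genome)
  expect_equal(nrow(clean), 0)

  # flip the phase distal to 6 Mbp on chrA: reads there get swapped calls
  x <- 6e6
  v2 <- data.table::copy(v)
  sw <- v2$chrom == "chrA" & v2$pos > x
  tmp <- v2$hap1_allele[sw]
  v2[sw, hap1_allele := hap2_allele]
  v2[which(sw), hap2_allele := tmp]
  # tags come from the true phase; decoding with the flipped table mimics a
  # phasing error downstream of position x
  hp2 <- assign_pairs_haplotype(p, tag_reads_with_alleles(p, v), v2)
  flagged <- detect_phasing_switches(hp2, cfg$genome)
  expect_gt(nrow(flagged), 0)
  hit <- flagged[flagged$chrom == "chrA"]
  expect_true(any(hit$start <= x & hit$end >= x))

  # all-unknown reads: empty report
  hp3 <- data.table::copy(hp)
  hp3[, hap1 := "unknown"]; hp3[, hap2 := "unknown"]
  expect_equal(nrow(detect_phasing_switches(hp3, cfg$genome)), 0)
})
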