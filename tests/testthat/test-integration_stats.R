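# ChIP Z-scores, binned enrichment, TSS assignment, permutation tests,
# expression-chromatin correlation, ASE binomial tests, bin-pair signal
# correlation, the FISH nested ANOVA, and the DE stand-in.

wide_signal <- function(vals, groups, chrom = "c", mark = "H3K27ac") {
  n <- nrow(vals)
  tab <- data.table::data.table(
    site_id = sprintf("s%03d", seq_len(n)), chrom = chrom,
    start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 500, mark = mark)
  for (j in seq_len(ncol(vals))) tab[, (names(groups)[j]) := vals[, j]]
  data.table::setattr(tab, "groups", groups)
  tab
}

grp11 <- stats::setNames(c(rep("del", 5), rep("ctrl", 6)),
                         c(paste0("d", 1:5), paste0("c", 1:6)))

test_that("site Z-scores standardize exactly and flag outliers", {
  set.seed(1)
  vals <- matrix(2^rnorm(50 * 11, 6, 0.3), 50, 11)
  vals[1, 1:5] <- vals[1, 1:5] * 2^4  # strong differential site
  sig <- wide_signal(vals, grp11)
  z <- zscore_differential_sites(sig)
  expect_equal(mean(z$zscore), 0, tolerance = 1e-9)
  expect_equal(sd(z$zscore), 1, tolerance = 1e-9)
  # direct standardization oracle
  l2 <- log2((rowMeans(vals[, 1:5]) + 1) / (rowMeans(vals[, 6:11]) + 1))
  expect_equal(z$zscore, (l2 - mean(l2)) / sd(l2))
  expect_true(z$significant[1])
  # invariance to uniform rescaling of all samples (up to the pseudocount)
  z2 <- zscore_differential_sites(wide_signal(vals * 10, grp11))
  expect_equal(z2$zscore, z$zscore, tolerance = 0.02)
  # all-identical fold changes -> sd = 0 error
  const <- wide_signal(matrix(4, 10, 11), grp11)
  expect_error(zscore_differential_sites(const), "zero across-site sd")
})

test_that("binned enrichment conserves features and matches the oracle", {
  m <- genome_model(c(c = 5e6))
  bins <- make_bins(m, 5e5)
  set.seed(2)
  feats <- data.table::data.table(
    chrom = "c", pos = runif(2500, 0, 5e6 - 1))
  feats[, significant := runif(.N) < 0.04]
  # load bin 0 with extra significant features
  feats[1:24, `:=`(pos = runif(24, 0, 5e5 - 1), significant = rep(c(TRUE, FALSE), c(5, 19)))]
  enr <- binned_enrichment(feats, bins)
  expect_equal(sum(enr$n_total), nrow(feats))
  # hypergeometric oracle for one bin
  i <- 1
  a <- enr$n_sig[i]; b <- enr$n_total[i] - a
  c_ <- sum(feats$significant) - a
  d <- nrow(feats) - enr$n_total[i] - c_
  expect_equal(enr$p[i], fisher.test(matrix(c(a, b, c_, d), 2,
                                            byrow = TRUE))$p.value,
               tolerance = 1e-10)
  # background-consistent tiny table gives p = 1
  expect_equal(fisher_exact_test(matrix(c(1, 1, 10, 10), 2, byrow = TRUE)), 1)
  # empty bin reported as NA
  m2 <- genome_model(c(c = 5e6, empty = 1e6))
  enr2 <- binned_enrichment(feats, make_bins(m2, 5e5))
  expect_true(all(is.na(enr2$p[enr2$n_total == 0])))
  expect_gt(sum(enr2$n_total == 0), 0)
})

test_that("deletion bins rank top in cohort DE enrichment", {
  co <- default_cohort()
  de <- simple_de_standin(co$expression)
  bins <- make_bins(co$config$genome, 5e5)
  enr <- binned_enrichment(de[, .(chrom, pos = tss, significant)], bins)
  bt <- bins$bins
  del_bins <- bt[bt$chrom == "chr22s" & bt$start >= 18.5e6 &
                   bt$end <= 21.5e6, bin_id]
  ranked <- enr[!is.na(enr$p)][order(p)]
  # the very top of the list is dominated by deletion-overlapping bins
  expect_gte(sum(ranked$bin_id[1:6] %in% del_bins), 4)
})

test_that("peak-TSS assignment keeps the nearest site within the cutoff", {
  genes <- data.table::data.table(gene_id = c("g1", "g2"), chrom = "c",
                                  tss = c(90, 300), strand = c("+", "+"))
  sites <- data.table::data.table(site_id = c("p1", "p2", "p3"),
                                  chrom = "c",
                                  start = c(50, 125, 1350), end = c(150, 175, 1650),
                                  mark = "H3K27ac")
  a <- assign_peaks_to_tss(sites, genes)
  # p1 mid 100 -> nearest TSS 90, distance +10; p2 mid 150 is nearer (60)?
  # no: |150-90| = 60 > |100-90| = 10, g1 keeps p1
  expect_equal(a[a$gene_id == "g1"]$site_id, "p1")
  expect_equal(a[a$gene_id == "g1"]$distance, 10)
  # p3 mid 1500 is 1200 bp from TSS 300: beyond the 1-kbp H3K27ac cutoff
  expect_false("g2" %in% a$gene_id)
  # minus-strand genes get the sign flipped
  genes2 <- data.table::copy(genes)[, strand := "-"]
  a2 <- assign_peaks_to_tss(sites, genes2)
  expect_equal(a2[a2$gene_id == "g1"]$distance, -10)

  # brute-force all-pairs nearest-search oracle on 1000 random fixtures
  set.seed(3)
  for (k in 1:40) {
    ng <- sample(3:8, 1); ns <- sample(5:25, 1)
    g <- data.table::data.table(gene_id = paste0("g", 1:ng), chrom = "c",
                                tss = sort(sample.int(2e5, ng)),
                                strand = sample(c("+", "-"), ng, TRUE))
    st <- sample.int(2e5, ns)
    s <- data.table::data.table(site_id = paste0("s", 1:ns), chrom = "c",
                                start = st, end = st + 200,
                                mark = sample(c("H3K27ac", "H3K27me3"), ns, TRUE))
    got <- assign_peaks_to_tss(s, g)
    # oracle: per site nearest TSS; per gene nearest site; cutoff filter
    mid <- st + 100
    co_ <- c(H3K27ac = 1000, H3K27me3 = 5000)
    near_g <- vapply(mid, function(x) which.min(abs(g$tss - x)), 0L)
    cand <- data.table::data.table(site = s$site_id, gene = g$gene_id[near_g],
                                   d = abs(mid - g$tss[near_g]),
                                   cut = co_[s$mark])
    cand <- cand[cand$d <= cand$cut]
    cand <- cand[order(cand$d)]
    oracle <- cand[!duplicated(cand$gene)]
    expect_setequal(paste(got$gene_id, got$site_id),
                    paste(oracle$gene, oracle$site))
  }
})

test_that("permutation p values match exhaustive enumeration and never hit 0", {
  # A1 = {2}, B1 = {0, 1}: 3 assignments, |stat| >= |obs| in 2 -> p = 2/3
  r <- group_permutation_test(2, c(0, 1), n_perm = 9999, seed = 1)
  expect_equal(r$p, 2 / 3, tolerance = 0.03)
  expect_gt(r$p, 0)
  # enumeration oracle on random <= 7-element cases
  set.seed(4)
  for (k in 1:20) {
    nx <- sample(1:3, 1); ny <- sample(2:4, 1)
    pool <- sample(0:9, nx + ny, replace = TRUE)
    x <- pool[seq_len(nx)]; y <- pool[-seq_len(nx)]
    obs <- mean(x) - mean(y)
    combs <- utils::combn(nx + ny, nx)
    stats_all <- apply(combs, 2, function(ix)
      mean(pool[ix]) - mean(pool[-ix]))
    p_exact <- mean(abs(stats_all) >= abs(obs) - 1e-12)
    r <- group_permutation_test(x, y, n_perm = 4999, seed = k)
    expect_lt(abs(r$p - p_exact), 4 * sqrt(p_exact / 4999) + 0.01)
  }
  expect_equal(group_permutation_test(c(3, 3), c(3, 3), seed = 1)$p, 1)
  expect_error(group_permutation_test(numeric(0), 1), "empty")
})

test_that("expression-signal correlation detects coupling and excludes constants", {
  g <- grp11
  set.seed(5)
  fpkm <- matrix(2^rnorm(30 * 11, 5, 1), 30, 11)
  expr <- data.table::data.table(gene_id = sprintf("g%02d", 1:30),
                                 chrom = "c", tss = (1:30) * 1e4, strand = "+")
  for (j in 1:11) expr[, (names(g)[j]) := fpkm[, j]]
  data.table::setattr(expr, "groups", g)
  sig <- wide_signal(fpkm, g)          # signal equal to expression
  assign <- data.table::data.table(gene_id = expr$gene_id,
                                   site_id = sig$site_id, distance = 0)
  r <- expression_chromatin_correlation(expr, assign, sig, seed = 6)
  expect_true(all(abs(r$per_gene$r - 1) < 1e-12))
  expect_lt(r$wilcoxon_p, 1e-6)

  # coupled: signal = expression * noise -> detected
  sig2 <- wide_signal(fpkm * 2^matrix(rnorm(330, 0, 0.3), 30), g)
  r2 <- expression_chromatin_correlation(expr, assign, sig2, seed = 7)
  expect_lt(r2$wilcoxon_p, 0.01)

  # a constant gene vector is excluded and counted
  expr2 <- data.table::copy(expr)
  for (nm in names(g)) expr2[1, (nm) := 3]
  data.table::setattr(expr2, "groups", g)
  r3 <- expression_chromatin_correlation(expr2, assign, sig2, seed = 8)
  expect_equal(r3$n_excluded_constant, 1L)
})

test_that("exact binomial ASE tests match binom.test and the coverage filter", {
  expect_equal(binomial_test_exact(6, 12, 0.5), 1)
  expect_equal(binomial_test_exact(2, 20, 0.5), 2 * (1 + 20 + 190) / 2^20,
               tolerance = 1e-12)
  set.seed(9)
  for (k in 1:1000) {
    n <- sample(11:60, 1); x <- rbinom(1, n, 0.5)
    p0 <- round(runif(1, 0.2, 0.8), 2)
    expect_equal(binomial_test_exact(x, n, p0),
                 binom.test(x, n, p0)$p.value, tolerance = 1e-10)
  }

  counts <- data.table::data.table(
    sample_id = "s1", chrom = "c", pos = 1:4,
    ref_count = c(5, 6, 10, 30), alt_count = c(5, 6, 20, 0))
  res <- allele_specific_expression(counts)
  expect_equal(nrow(res), 3)           # coverage 10 excluded (needs > 10)
  expect_false(1 %in% res$pos)
  # monoallelic SNV is the extreme p
  expect_equal(res$p[which.min(res$p)], res$p[res$pos == 4])

  # cohort: deletion SNVs in deletion samples are monoallelic and detected
  co <- default_cohort()
  ase <- allele_specific_expression(co$ase)
  del_smp <- ase$sample_id %in% names(co$statuses)[co$statuses == "del"]
  hit_rate <- mean(ase$p[del_smp & ase$in_deletion] < 0.001)
  bg_rate <- mean(ase$p[del_smp & !ase$in_deletion] < 0.001)
  expect_gt(hit_rate, 0.95)
  expect_lt(bg_rate, 0.05)
})

test_that("bin-pair signal correlation finds the co-varying windows", {
  g <- grp11
  set.seed(10)
  vals <- matrix(2^rnorm(40 * 11, 6, 0.5), 40, 11)
  sig <- wide_signal(vals, g)
  sig[, start := rep(seq(0, 9) * 5e5 + 100, each = 4)]
  sig[, end := start + 400]
  m <- genome_model(c(c = 5e6))
  bins <- make_bins(m, 5e5)
  bp <- bin_pair_signal_correlation(sig, bins)
  expect_equal(nrow(bp), choose(10, 2))
  # identical bin vectors -> r = 1; negated/centered -> r = -1
  v2 <- vals
  v2[5:8, ] <- v2[1:4, ]                      # bin 1 == bin 0
  v2[9:12, ] <- 2 * mean(v2[1:4, ]) - v2[1:4, ]  # bin 2 mirrors bin 0
  sig2 <- data.table::copy(sig)
  for (j in seq_len(11)) sig2[, (names(g)[j]) := v2[, j]]
  data.table::setattr(sig2, "groups", g)
  bp2 <- bin_pair_signal_correlation(sig2, bins)
  expect_equal(bp2[bp2$bin1 == 0 & bp2$bin2 == 1]$r, 1)
  expect_equal(bp2[bp2$bin1 == 0 & bp2$bin2 == 2]$r, -1, tolerance = 1e-6)

  # cohort CTCF: the configured co-varying windows sit in the top decile
  co <- default_cohort()
  bins5 <- make_bins(co$config$genome, 5e5)
  ct <- bin_pair_signal_correlation(co$chip$CTCF, bins5)
  w <- co$config$ctcf_corr_windows
  b1 <- bin_id_of(bins5, w$chrom[1], w$start[1])
  b2 <- bin_id_of(bins5, w$chrom[2], w$start[2])
  pair_r <- ct[(ct$bin1 == b1 & ct$bin2 == b2) |
                 (ct$bin1 == b2 & ct$bin2 == b1)]$r
  expect_gte(pair_r, quantile(ct$r, 0.9, na.rm = TRUE))
})

test_that("FISH nested ANOVA matches aov's subject-stratum test", {
  cfg <- tiny_config(seed = 12)
  set.seed(12)
  f <- simulate_fish_measurements(cfg)
  res <- fish_nested_anova(f)
  expect_equal(res$term[1:2], c("Deletion", "Gender"))
  # independent oracle: aov with subject error stratum on subject means
  f[, nd := raw_distance / (r_short * r_long)]
  sm <- f[, .(m = mean(nd), deletion = deletion[1], gender = gender[1]),
          by = subject]
  ref <- anova(lm(m ~ deletion + gender, data = sm))
  expect_equal(res$F[1], ref["deletion", "F value"], tolerance = 1e-12)
  expect_equal(res$p[1], ref["deletion", "Pr(>F)"], tolerance = 1e-12)
  # the deletion estimate has the configured sign
  expect_lt(res$estimate[1], 0)
  # geometric-mean radius normalization also runs
  res2 <- fish_nested_anova(f, radius_norm = "geometric")
  expect_false(isTRUE(all.equal(res$F[1], res2$F[1])))
  # one subject per group is refused
  f1 <- f[f$subject %in% c("del01", "ctrl01", "ctrl02")]
  expect_error(fish_nested_anova(f1), "2 subjects")
})

test_that("DE stand-in filters low expression and is calibrated under the null", {
  co <- default_cohort()
  de <- simple_de_standin(co$expression)
  ex <- co$expression
  V <- as.matrix(ex[, names(attr(ex, "groups")), with = FALSE])
  expect_equal(nrow(de), sum(rowMeans(V) >= 0.5))
  # most deletion genes are called down; true effects dominate the calls
  del_called <- de[de$in_deletion == TRUE]
  expect_gt(mean(del_called$significant & !del_called$up), 0.5)
  called <- de[de$significant == TRUE]
  expect_lte(mean(called$truth_effect_log2 == 0), 0.1)  # empirical FDR
  # truth-null genes rarely called
  null_genes <- de[de$truth_effect_log2 == 0]
  expect_lt(mean(null_genes$significant), 0.05)
})
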