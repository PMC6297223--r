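# Integration of ChIP-seq, RNA-seq, allele-specific expression and 3D FISH
# with the contact analyses: Z-score differential sites, binned Fisher
# enrichment, peak-TSS assignment, permutation coupling tests, exact
# binomial allele tests, bin-pair signal correlations, and the nested
# FISH ANOVA.

sample_cols <- function(tab) {
  names(attr(tab, "groups"))
}

group_of <- function(tab) attr(tab, "groups")

#' Z-score differential binding sites
#'
#' Per mark, the log2 fold change of mean normalized counts
#' (deletion vs control, pseudocount `eps`) is standardized across sites to
#' Z-scores; sites beyond the cutoff are flagged as differentially bound.
#'
#' @param signal wide signal table (one mark) with a `groups` attribute.
#' @param z_cutoff |Z| cutoff (default 2; the TSS-side analyses use 1 for
#'   H3K27ac and 2 for H3K27me3).
#' @param eps pseudocount on group means.
#' @return the table with `log2fc`, `zscore`, `significant` columns added.
#' @export
zscore_differential_sites <- function(signal, z_cutoff = 2, eps = 1) {
  g <- group_of(signal)
  if (sum(g == "del") < 2 || sum(g == "ctrl") < 2)
    stop("need at least 2 samples per group")
  out <- data.table::copy(signal)
  vd <- as.matrix(out[, names(g)[g == "del"], with = FALSE])
  vc <- as.matrix(out[, names(g)[g == "ctrl"], with = FALSE])
  l2fc <- log2((rowMeans(vd) + eps) / (rowMeans(vc) + eps))
  s <- stats::sd(l2fc)
  if (!is.finite(s) || s == 0) stop("zero across-site sd of log2 fold changes")
  out[, log2fc := l2fc]
  out[, zscore := (l2fc - mean(l2fc)) / s]
  out[, significant := abs(zscore) > z_cutoff]
  data.table::setattr(out, "groups", g)
  out[]
}

#' Binned Fisher enrichment of flagged features
#'
#' For each bin, tests the 2x2 table of (flagged, unflagged) features
#' inside versus outside the bin against the whole-genome background, with
#' BH correction across non-empty bins.
#'
#' @param features data.table with `chrom`, `pos`, `significant`.
#' @param bins a `bin_scheme` (typically 500 kbp).
#' @return per-bin data.table (`bin_id`, `chrom`, `start`, `end`,
#'   `n_total`, `n_sig`, `p`, `fdr`); empty bins get `NA` p.
#' @export
binned_enrichment <- function(features, bins) {
  f <- data.table::as.data.table(features)
  f[, bin_id := bin_id_of(bins, chrom, pos)]
  agg <- f[, .(n_total = .N, n_sig = sum(significant)), by = bin_id]
  out <- merge(bins$bins, agg, by = "bin_id", all.x = TRUE)
  out[is.na(n_total), `:=`(n_total = 0L, n_sig = 0L)]
  tot_sig <- sum(f$significant); tot <- nrow(f)
  out[, p := NA_real_]
  nz <- which(out$n_total > 0)
  out$p[nz] <- vapply(nz, function(i) {
    a <- out$n_sig[i]; b <- out$n_total[i] - a
    c_ <- tot_sig - a; d <- (tot - out$n_total[i]) - c_
    fisher_exact_test(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))
  }, 0)
  out[, fdr := NA_real_]
  out$fdr[nz] <- stats::p.adjust(out$p[nz], "BH")
  out[]
}

#' Assign binding sites to their nearest TSS
#'
#' Each site is assigned to the nearest TSS by midpoint distance (signed by
#' gene strand, downstream positive); when a gene attracts several sites
#' only the nearest is retained, and assignments beyond the mark-specific
#' cutoff are dropped (the conventional windows are +/-1 kbp for H3K27ac
#' and +/-5 kbp for H3K27me3).
#'
#' @param sites signal table with `site_id`, `chrom`, `start`, `end`,
#'   `mark`.
#' @param genes expression table with `gene_id`, `chrom`, `tss`, `strand`.
#' @param cutoff named vector of per-mark distance cutoffs in bp.
#' @return data.table (`gene_id`, `site_id`, `distance`).
#' @export
assign_peaks_to_tss <- function(sites, genes,
                                cutoff = c(H3K27ac = 1000, H3K27me3 = 5000)) {
  s <- data.table::as.data.table(sites)[, .(site_id, chrom, start, end, mark)]
  s[, mid := (start + end) / 2]
  out <- list()
  for (cn in unique(s$chrom)) {
    g <- genes[genes$chrom == cn]
    if (nrow(g) == 0L) next
    data.table::setorder(g, tss)
    sc <- s[s$chrom == cn]
    lo <- findInterval(sc$mid, g$tss)
    lo_d <- ifelse(lo >= 1, abs(sc$mid - g$tss[pmax(lo, 1)]), Inf)
    hi_d <- ifelse(lo < nrow(g), abs(sc$mid - g$tss[pmin(lo + 1, nrow(g))]), Inf)
    nearest <- ifelse(lo_d <= hi_d, pmax(lo, 1), pmin(lo + 1, nrow(g)))
    sc[, gene_id := g$gene_id[nearest]]
    sc[, gdist := sc$mid - g$tss[nearest]]
    sc[, distance := ifelse(g$strand[nearest] == "+", gdist, -gdist)]
    out[[cn]] <- sc[, .(gene_id, site_id, mark, distance)]
  }
  a <- data.table::rbindlist(out)
  a <- a[abs(distance) <= cutoff[mark]]
  # per gene keep the nearest site only
  a <- a[order(gene_id, abs(distance))]
  a <- a[!duplicated(gene_id)]
  a[, mark := NULL]
  a[]
}

#' Permutation test for a difference of group means
#'
#' Two-sided p by random redistribution of group membership within the
#' compared pair, with the add-one estimator
#' `p = (1 + #(|perm| >= |obs|)) / (n_perm + 1)`, so p is never zero.
#'
#' @param x,y numeric vectors of the two groups.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list `(statistic, p, n_perm)`.
#' @export
group_permutation_test <- function(x, y, n_perm = 9999, seed = 1) {
  if (!length(x) || !length(y)) stop("a compared group is empty")
  obs <- mean(x) - mean(y)
  pool <- c(x, y); nx <- length(x)
  set.seed(seed)
  cnt <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(length(pool), nx)
    stat <- mean(pool[idx]) - mean(pool[-idx])
    if (abs(stat) >= abs(obs) - 1e-12) cnt <- cnt + 1L
  }
  list(statistic = obs, p = (1 + cnt) / (n_perm + 1), n_perm = n_perm)
}

#' Four-group coupling test between expression and a histone mark
#'
#' Splits genes into significantly / non-significantly up- and
#' down-regulated groups (A1, B1, A2, B2) and compares the Z-transformed
#' TSS-site fold changes (or any supplied per-gene value) of A1 vs B1 and
#' A2 vs B2 by permutation.
#'
#' @param values named numeric vector (per gene).
#' @param sig logical vector: gene significantly differentially expressed.
#' @param up logical vector: gene upregulated in the deletion group.
#' @param n_perm,seed passed to [group_permutation_test()].
#' @return data.table with one row per comparison (`up`, `down`).
#' @export
four_group_coupling_test <- function(values, sig, up, n_perm = 9999, seed = 1) {
  stopifnot(length(values) == length(sig), length(sig) == length(up))
  res <- list()
  for (dir in c(TRUE, FALSE)) {
    a <- values[sig & up == dir]
    b <- values[!sig & up == dir]
    r <- group_permutation_test(a, b, n_perm,
                                seed = seed + as.integer(!dir))
    res[[length(res) + 1L]] <- data.table::data.table(
      comparison = if (dir) "up" else "down",
      n_sig = length(a), n_nonsig = length(b),
      mean_sig = mean(a), mean_nonsig = mean(b),
      statistic = r$statistic, p = r$p)
  }
  data.table::rbindlist(res)
}

#' Correlation between gene expression and TSS-site histone signal
#'
#' Per assigned gene, the Pearson correlation between FPKM and the TSS
#' site's normalized counts across shared samples; the background is the
#' same correlation after permuting that gene's FPKM across samples
#' (`n_bg_perm` draws per gene); observed and background distributions are
#' compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param expr expression table.
#' @param assignment from [assign_peaks_to_tss()].
#' @param signal signal table of the assigned mark.
#' @param n_bg_perm background permutations per gene (default 10).
#' @param seed integer seed.
#' @return list `(per_gene, background, wilcoxon_p, n_excluded_constant)`.
#' @export
expression_chromatin_correlation <- function(expr, assignment, signal,
                                             n_bg_perm = 10, seed = 1) {
  shared <- intersect(sample_cols(expr), sample_cols(signal))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  e <- as.matrix(data.table::as.data.table(expr)[, shared, with = FALSE])
  rownames(e) <- expr$gene_id
  s <- as.matrix(data.table::as.data.table(signal)[, shared, with = FALSE])
  rownames(s) <- signal$site_id
  a <- assignment[assignment$gene_id %in% rownames(e) &
                    assignment$site_id %in% rownames(s)]
  set.seed(seed)
  obs <- numeric(0); bg <- numeric(0); gene_ids <- character(0)
  n_const <- 0L
  for (k in seq_len(nrow(a))) {
    fv <- e[a$gene_id[k], ]; sv <- s[a$site_id[k], ]
    if (stats::sd(fv) == 0 || stats::sd(sv) == 0) {
      n_const <- n_const + 1L
      next
    }
    obs <- c(obs, stats::cor(fv, sv))
    gene_ids <- c(gene_ids, a$gene_id[k])
    bg <- c(bg, vapply(seq_len(n_bg_perm),
                       function(i) stats::cor(sample(fv), sv), 0))
  }
  if (!length(obs)) stop("no testable genes")
  w <- stats::wilcox.test(obs, bg, alternative = "two.sided", exact = FALSE)
  list(per_gene = data.table::data.table(gene_id = gene_ids, r = obs),
       background = bg, wilcoxon_p = w$p.value,
       n_excluded_constant = n_const)
}

#' Exact two-sided binomial test
#'
#' Sums the probabilities of all outcomes as or less likely than the
#' observed count under `Binomial(n, p0)` (standard minimum-likelihood
#' two-sided rule with 1e-7 relative tolerance).
#'
#' @param x observed count.
#' @param n trials.
#' @param p0 null success probability.
#' @return two-sided p value.
#' @export
binomial_test_exact <- function(x, n, p0) {
  stopifnot(x >= 0, x <= n, p0 > 0, p0 < 1)
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

#' Allele-specific expression by exact binomial tests
#'
#' Per sample, the background alternative-allele frequency `p0` is the mean
#' of `alt/(ref+alt)` over all qualifying heterozygous SNVs; each SNV with
#' read coverage above `min_coverage` is then tested against `p0`.
#'
#' @param counts data.table (`sample_id`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`).
#' @param min_coverage inclusion threshold; SNVs with coverage less than or
#'   equal to this are excluded (default 10, i.e. coverage > 10 required).
#' @return data.table of tested SNVs with `p0`, `alt_freq`, `p` columns.
#' @export
allele_specific_expression <- function(counts, min_coverage = 10) {
  dt <- data.table::as.data.table(counts)
  dt[, coverage := ref_count + alt_count]
  dt <- dt[coverage > min_coverage]
  if (nrow(dt) == 0L) stop("no SNVs pass the coverage filter")
  dt[, p0 := mean(alt_count / coverage), by = sample_id]
  if (any(dt$p0 <= 0 | dt$p0 >= 1))
    stop("degenerate background allele frequency")
  dt[, p := mapply(binomial_test_exact, alt_count, coverage, p0)]
  dt[, alt_freq := alt_count / coverage]
  dt[]
}

#' Pearson correlation of epigenetic signal between genomic bins
#'
#' Per bin, the mean normalized count over all sites of a mark per sample;
#' then the Pearson correlation (and its t-transform p value) across
#' samples for every pair of bins on the same chromosome.
#'
#' @param signal signal table of one mark.
#' @param bins a `bin_scheme` (typically 500 kbp).
#' @return data.table (`bin1`, `bin2`, `r`, `p`); bins with constant
#'   vectors give `NA`.
#' @export
bin_pair_signal_correlation <- function(signal, bins) {
  g <- group_of(signal)
  if (length(g) < 3) stop("need at least 3 samples")
  s <- data.table::as.data.table(signal)
  s[, bin_id := bin_id_of(bins, chrom, (start + end) / 2)]
  agg <- s[, lapply(.SD, mean), by = bin_id, .SDcols = names(g)]
  binfo <- bins$bins[match(agg$bin_id, bins$bins$bin_id)]
  M <- as.matrix(agg[, names(g), with = FALSE])
  n <- length(g)
  out <- list()
  for (cn in unique(binfo$chrom)) {
    idx <- which(binfo$chrom == cn)
    if (length(idx) < 2) next
    cm <- suppressWarnings(stats::cor(t(M[idx, , drop = FALSE])))
    ut <- which(upper.tri(cm), arr.ind = TRUE)
    r <- cm[ut]
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    p[is.na(r)] <- NA_real_
    out[[cn]] <- data.table::data.table(
      bin1 = agg$bin_id[idx[ut[, 1]]], bin2 = agg$bin_id[idx[ut[, 2]]],
      r = r, p = p)
  }
  data.table::rbindlist(out)
}

#' Nested ANOVA for 3D FISH distances
#'
#' Distances are normalized by the product of the shortest and longest
#' nuclear radius, then modelled as
#' `Distance ~ Deletion + Gender + Deletion/Subject` with Subject a random
#' effect nested in Deletion. The Deletion (and Gender) effect is tested
#' at the subject level - an ANOVA on subject means, which is the
#' expected-mean-squares test of the group effect against between-subject
#' variation - so cell-level pseudoreplication cannot inflate it.
#'
#' @param fish data.table with `subject`, `deletion`, `gender`,
#'   `raw_distance`, `r_short`, `r_long`.
#' @param radius_norm `"product"` (default) or `"geometric"`
#'   (`sqrt(r_short*r_long)`).
#' @return data.table of effects (`term`, `df1`, `df2`, `F`, `p`,
#'   `estimate`); `estimate` for Deletion is the difference of group means
#'   on the normalized scale.
#' @export
fish_nested_anova <- function(fish, radius_norm = c("product", "geometric")) {
  radius_norm <- match.arg(radius_norm)
  dt <- data.table::as.data.table(fish)
  dt[, norm_distance := raw_distance /
       (if (radius_norm == "product") r_short * r_long
        else sqrt(r_short * r_long))]
  subj <- dt[, .(m = mean(norm_distance), n_cells = .N,
                 deletion = deletion[1], gender = gender[1]), by = subject]
  if (min(table(subj$deletion)) < 2)
    stop("need at least 2 subjects per deletion group")
  fit <- stats::lm(m ~ deletion + gender, data = subj)
  an <- stats::anova(fit)
  est <- subj[, mean(m[deletion == TRUE]) - mean(m[deletion == FALSE])]
  # cell-level residual stratum, reported for completeness
  cell_res_df <- nrow(dt) - nrow(subj)
  cell_res_ms <- dt[, {
    mm <- mean(norm_distance); sum((norm_distance - mm)^2)
  }, by = subject][, sum(V1)] / cell_res_df
  out <- data.table::data.table(
    term = c("Deletion", "Gender", "Subject(Deletion)", "Residual(cells)"),
    df1 = c(1, 1, an["Residuals", "Df"], cell_res_df),
    df2 = c(an["Residuals", "Df"], an["Residuals", "Df"], NA, NA),
    F = c(an["deletion", "F value"], an["gender", "F value"], NA, NA),
    p = c(an["deletion", "Pr(>F)"], an["gender", "Pr(>F)"], NA, NA),
    estimate = c(est, NA, an["Residuals", "Mean Sq"], cell_res_ms))
  out[]
}

#' Simple differential-expression stand-in
#'
#' Filters out low-expression genes (mean FPKM below `fpkm_min`), applies
#' the Welch t test to `log2(FPKM + 1)` per gene, and BH-adjusts. This is
#' plumbing to provide significance flags for the enrichment and coupling
#' analyses, not a full RNA-seq differential-expression model.
#'
#' @param expr expression table with a `groups` attribute.
#' @param fpkm_min expression filter (default 0.5).
#' @param fdr significance level on the BH-adjusted p (default 0.05).
#' @return the filtered table with `log2fc`, `p`, `fdr_p`, `significant`,
#'   `up` columns.
#' @export
simple_de_standin <- function(expr, fpkm_min = 0.5, fdr = 0.05) {
  g <- group_of(expr)
  if (sum(g == "del") < 2 || sum(g == "ctrl") < 2)
    stop("need at least 2 samples per group")
  out <- data.table::copy(expr)
  V <- as.matrix(out[, names(g), with = FALSE])
  out <- out[rowMeans(V) >= fpkm_min]
  V <- log2(as.matrix(out[, names(g), with = FALSE]) + 1)
  gd <- which(g == "del"); gc <- which(g == "ctrl")
  p <- apply(V, 1, function(v) welch_t_test(v[gd], v[gc])$p)
  out[, log2fc := rowMeans(V[, gd, drop = FALSE]) -
        rowMeans(V[, gc, drop = FALSE])]
  out[, p := p]
  out[, fdr_p := stats::p.adjust(p, "BH")]
  out[, significant := !is.na(fdr_p) & fdr_p < fdr]
  out[, up := log2fc > 0]
  data.table::setattr(out, "groups", g)
  out[]
}
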