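# Differential trans-contact testing between deletion and control groups,
# enrichment of significant contacts among the strongest contacts, and
# label-permutation controls.

#' Welch two-sample t test
#'
#' Unequal-variance statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value (the default behaviour of R's `t.test`, which is
#' what the group comparisons here standardize on). An equal-variance
#' pooled option is available.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal use the pooled equal-variance form.
#' @return list `(t, df, p, excluded, reason)`; pairs where both groups
#'   have zero variance are excluded rather than tested.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need at least 2 observations per group")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                excluded = TRUE, reason = "zero variance in both groups"))
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mean(x) - mean(y)) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), excluded = FALSE,
       reason = NA_character_)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test: with margins fixed, the p value is the sum of
#' probabilities of all tables as or less probable than the observed one
#' (with the standard 1e-7 relative tolerance on "as probable").
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p value.
#' @export
fisher_exact_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(dim(tab) == c(2, 2))
  if (any(tab < 0) || any(tab != floor(tab))) stop("counts must be non-negative integers")
  m <- sum(tab[1, ])          # row-1 margin
  n <- sum(tab[2, ])          # row-2 margin
  k <- sum(tab[, 1])          # col-1 margin
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  d <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
}

#' Differential trans-contact testing
#'
#' Tests every inter-chromosomal bin pair with at least one supporting raw
#' read pair in every sample, using the two-sided Welch t test on the
#' depth-scaled values, at a fixed significance threshold (no multiplicity
#' correction; a Benjamini-Hochberg column is provided for reuse).
#'
#' @param matrices named list of depth-scaled `contact_matrix` objects, one
#'   per sample, with `raw` columns (from [depth_normalize()]).
#' @param labels character vector (parallel to `matrices`) of `"del"` /
#'   `"ctrl"` group labels.
#' @param p_threshold significance threshold (default 1e-4).
#' @param var_equal passed to the t test.
#' @return data.table of tested pairs (`bin1`, `bin2`, `mean_del`,
#'   `mean_ctrl`, `strength`, `t`, `df`, `p`, `p_bh`, `significant`) with a
#'   `summary` attribute.
#' @export
differential_trans_contacts <- function(matrices, labels, p_threshold = 1e-4,
                                        var_equal = FALSE) {
  stopifnot(length(matrices) == length(labels))
  if (sum(labels == "del") < 2 || sum(labels == "ctrl") < 2)
    stop("need at least 2 samples per group")
  bins <- matrices[[1]]$bins
  for (m in matrices) {
    if (m$normalization != "depth_scaled") stop("matrices must be depth_scaled")
    if (!"raw" %in% names(m$entries)) stop("raw counts missing")
    if (!same_scheme(bins, m$bins)) stop("bin scheme mismatch")
  }
  chrom_of <- bins$bins$chrom
  # inner join across samples keeps only cells with a raw pair everywhere
  cells <- NULL
  for (s in seq_along(matrices)) {
    e <- matrices[[s]]$entries[, .(bin1, bin2, value, raw)]
    data.table::setnames(e, c("value", "raw"),
                         c(paste0("v", s), paste0("r", s)))
    cells <- if (is.null(cells)) e else
      merge(cells, e, by = c("bin1", "bin2"), all = FALSE)
  }
  cells <- cells[chrom_of[bin1 + 1L] != chrom_of[bin2 + 1L]]
  rcols <- paste0("r", seq_along(matrices))
  keep <- rowSums(as.matrix(cells[, ..rcols]) >= 1) == length(matrices)
  cells <- cells[keep]
  if (nrow(cells) == 0L)
    stop("no trans cells pass the inclusion filter")
  V <- as.matrix(cells[, paste0("v", seq_along(matrices)), with = FALSE])
  gd <- which(labels == "del"); gc <- which(labels == "ctrl")
  if (var_equal) {
    res <- t(apply(V, 1, function(v) {
      r <- welch_t_test(v[gd], v[gc], var_equal = TRUE)
      c(r$t, r$df, r$p)
    }))
    tt <- res[, 1]; df <- res[, 2]; pp <- res[, 3]
  } else {
    nd <- length(gd); nc <- length(gc)
    md <- rowMeans(V[, gd, drop = FALSE]); mc <- rowMeans(V[, gc, drop = FALSE])
    vd <- (rowSums(V[, gd, drop = FALSE]^2) - nd * md^2) / (nd - 1)
    vc <- (rowSums(V[, gc, drop = FALSE]^2) - nc * mc^2) / (nc - 1)
    vd <- pmax(vd, 0); vc <- pmax(vc, 0)
    se2 <- vd / nd + vc / nc
    tt <- ifelse(se2 > 0, (md - mc) / sqrt(se2), NA_real_)
    df <- ifelse(se2 > 0,
                 se2^2 / ((vd / nd)^2 / (nd - 1) + (vc / nc)^2 / (nc - 1)),
                 NA_real_)
    pp <- 2 * stats::pt(-abs(tt), df)
  }
  out <- cells[, .(bin1, bin2)]
  out[, mean_del := rowMeans(V[, gd, drop = FALSE])]
  out[, mean_ctrl := rowMeans(V[, gc, drop = FALSE])]
  out[, strength := rowMeans(V)]
  out[, t := tt]; out[, df := df]; out[, p := pp]
  excluded <- is.na(pp)
  out <- out[!excluded]
  out[, p_bh := stats::p.adjust(p, "BH")]
  out[, significant := p < p_threshold]
  data.table::setattr(out, "summary", list(
    n_tested = nrow(out), n_excluded_zero_var = sum(excluded),
    n_significant = sum(out$significant), p_threshold = p_threshold))
  out[]
}

#' Enrichment of differential contacts among the strongest contacts
#'
#' Ranks tested pairs by mean depth-scaled value across all samples, takes
#' the top `1 - q` quantile (default top 5%), and tests the 2x2
#' significant-by-top table with the exact Fisher test.
#'
#' @param result table from [differential_trans_contacts()].
#' @param q strength quantile defining "strongest" (default 0.95).
#' @return list `(table, p, n_top, n_significant, n_overlap)`.
#' @export
strongest_contact_enrichment <- function(result, q = 0.95) {
  if (nrow(result) < 20) stop("fewer than 20 included pairs")
  thr <- stats::quantile(result$strength, q, names = FALSE)
  top <- result$strength >= thr
  sig <- result$significant
  tab <- matrix(c(sum(sig & top), sum(sig & !top),
                  sum(!sig & top), sum(!sig & !top)),
                2, 2, byrow = TRUE)
  dimnames(tab) <- list(c("significant", "not_significant"),
                        c("top_strength", "rest"))
  list(table = tab, p = fisher_exact_test(tab),
       n_top = sum(top), n_significant = sum(sig),
       n_overlap = sum(sig & top))
}

#' Label-permutation controls for the differential-trans analysis
#'
#' Re-runs the differential test and the strongest-contact enrichment under
#' permuted group labels: `swap10` permutes deletion/control status across
#' all samples (10 replicates), `within_ctrl3` / `within_del3` split one
#' group into two pseudo-groups (3 replicates).
#'
#' @param matrices,labels,p_threshold as in
#'   [differential_trans_contacts()].
#' @param scheme `"swap10"`, `"within_ctrl3"`, or `"within_del3"`.
#' @param seed integer seed.
#' @return data.table (`replicate`, `n_significant`, `enrichment_p`).
#' @export
label_swap_analysis <- function(matrices, labels,
                                scheme = c("swap10", "within_ctrl3",
                                           "within_del3"),
                                p_threshold = 1e-4, seed = 1) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  run_one <- function(mats, labs) {
    r <- differential_trans_contacts(mats, labs, p_threshold)
    p_en <- if (nrow(r) >= 20) strongest_contact_enrichment(r)$p else NA_real_
    c(n_significant = attr(r, "summary")$n_significant, enrichment_p = p_en)
  }
  reps <- list()
  if (scheme == "swap10") {
    for (k in 1:10) {
      repeat {
        labs <- sample(labels)
        if (!identical(labs, labels)) break
      }
      reps[[k]] <- run_one(matrices, labs)
    }
  } else {
    grp <- if (scheme == "within_ctrl3") "ctrl" else "del"
    idx <- which(labels == grp)
    if (length(idx) < 4) stop("group too small to split")
    n1 <- floor(length(idx) / 2)
    for (k in 1:3) {
      a <- sample(idx, n1)
      labs <- ifelse(seq_along(labels) %in% a, "del", "ctrl")
      reps[[k]] <- run_one(matrices[idx], labs[idx])
    }
  }
  out <- data.table::as.data.table(do.call(rbind, reps))
  out[, replicate := seq_len(.N)]
  data.table::setcolorder(out, "replicate")
  out[]
}
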