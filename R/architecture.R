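# A/B compartments (leading eigenvector of the contact correlation matrix)
# and topological domains (directionality-index segmentation) on cis
# contact matrices, optionally haplotype-specific.

# dense symmetric cis matrix for one chromosome, rows/cols = local bins
dense_cis <- function(cm, chrom) {
  sel <- which(cm$bins$bins$chrom == chrom)
  btab <- cm$bins$bins[sel]
  ids <- btab$bin_id
  n <- length(ids)
  M <- matrix(0, n, n)
  e <- cm$entries[bin1 %in% ids & bin2 %in% ids]
  i <- e$bin1 - ids[1] + 1L
  j <- e$bin2 - ids[1] + 1L
  M[cbind(i, j)] <- e$value
  M[cbind(j, i)] <- e$value
  attr(M, "bin_ids") <- ids
  attr(M, "starts") <- btab$start
  M
}

#' Observed-over-expected transformation of a cis matrix
#'
#' The expected value at separation `s` is the mean observed contact over
#' all unmasked cells at that separation; O/E divides each cell by its
#' separation's expectation. Masked bins (all-zero rows plus any explicit
#' mask, e.g. deletion bins on a deleted homolog) get `NaN` rows/columns.
#'
#' @param cm a `contact_matrix`.
#' @param chrom chromosome to transform (cis only).
#' @param mask_bins optional integer vector of global bin ids to mask.
#' @return dense O/E matrix with attributes `masked` (local indices) and
#'   `bin_ids`.
#' @export
observed_over_expected <- function(cm, chrom, mask_bins = NULL) {
  M <- dense_cis(cm, chrom)
  n <- nrow(M)
  ids <- attr(M, "bin_ids")
  masked <- which(rowSums(M) == 0)
  if (!is.null(mask_bins)) masked <- union(masked, which(ids %in% mask_bins))
  if (length(masked) == n) stop("all bins masked")
  ok <- setdiff(seq_len(n), masked)
  ok_vec <- rep(FALSE, n); ok_vec[ok] <- TRUE
  expected <- vapply(0:(n - 1), function(s) {
    i <- seq_len(n - s)
    use <- ok_vec[i] & ok_vec[i + s]
    if (!any(use)) return(NA_real_)
    mean(M[cbind(i[use], i[use] + s)])
  }, 0)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(expected[sep + 1L], n, n)
  OE <- M / E
  OE[E == 0 | is.na(E)] <- NaN
  OE[masked, ] <- NaN; OE[, masked] <- NaN
  attr(OE, "masked") <- masked
  attr(OE, "bin_ids") <- ids
  OE
}

#' A/B compartment call from the leading eigenvector
#'
#' Computes the Pearson correlation matrix of the O/E columns over unmasked
#' bins, takes the leading eigenvector of the symmetric eigendecomposition,
#' and orients its sign so that bins with higher values of the orientation
#' track (e.g. gene density) are positive; positive = A, negative = B.
#'
#' @param oe O/E matrix from [observed_over_expected()].
#' @param orientation numeric track over the same bins (full-length,
#'   masked entries ignored).
#' @return data.table (`bin_id`, `e1`, `label`) with `NA` rows for masked
#'   bins.
#' @export
compartment_pc1 <- function(oe, orientation) {
  n <- nrow(oe)
  masked <- attr(oe, "masked")
  ok <- setdiff(seq_len(n), masked)
  if (length(ok) < 10) stop("need at least 10 unmasked bins")
  sub <- oe[ok, ok, drop = FALSE]
  sds <- apply(sub, 2, stats::sd, na.rm = TRUE)
  if (all(!is.finite(sds) | sds < 1e-12))
    stop("no compartment signal: degenerate matrix")
  cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  e1 <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  o <- orientation[ok]
  if (stats::cor(e1, o) < 0) e1 <- -e1
  full <- rep(NA_real_, n); full[ok] <- e1
  lab <- rep(NA_character_, n)
  lab[ok] <- ifelse(e1 > 0, "A", ifelse(e1 < 0, "B", NA_character_))
  out <- data.table::data.table(bin_id = attr(oe, "bin_ids"),
                                e1 = full, label = lab)
  out[]
}

#' Directionality index of a cis contact matrix
#'
#' Per bin, with `A` the contact sum to the upstream window and `B` to the
#' downstream window and `E = (A+B)/2`, the index is
#' `sign(B-A) * ((A-E)^2/E + (B-E)^2/E)`; 0 where `A == B`. Bins whose
#' window is truncated by a chromosome end are flagged.
#'
#' @param cm a `contact_matrix`.
#' @param chrom chromosome.
#' @param window window width in bp (default 2 Mbp, the conventional
#'   choice for domain calling).
#' @return data.table (`bin_id`, `A`, `B`, `di`, `truncated`).
#' @export
directionality_index <- function(cm, chrom, window = 2e6) {
  M <- dense_cis(cm, chrom)
  n <- nrow(M)
  w <- as.integer(window %/% cm$bins$resolution)
  if (w < 2) stop("window must span at least 2 bins")
  A <- B <- numeric(n)
  for (i in seq_len(n)) {
    up <- seq.int(max(1L, i - w), i - 1L)
    dn <- seq.int(i + 1L, min(n, i + w))
    A[i] <- if (i > 1L) sum(M[i, up]) else 0
    B[i] <- if (i < n) sum(M[i, dn]) else 0
  }
  E <- (A + B) / 2
  di <- ifelse(A == B, 0,
               sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E))
  data.table::data.table(bin_id = attr(M, "bin_ids"), A = A, B = B, di = di,
                         truncated = seq_len(n) <= w | seq_len(n) > n - w)
}

# three-state maximum-score segmentation of the DI track: states are
# downstream-biased (+1), none (0), upstream-biased (-1); per-bin score is
# state * z(DI) and each state change costs `penalty` (in z units).
segment_di_states <- function(di, penalty) {
  sc <- stats::median(abs(di[di != 0]))
  if (!is.finite(sc) || sc == 0) sc <- 1
  z <- di / sc
  n <- length(z)
  states <- c(-1, 0, 1)
  score <- matrix(-Inf, 3, n)
  back <- matrix(0L, 3, n)
  score[, 1] <- states * z[1]
  for (t in 2:n) {
    for (s in 1:3) {
      cand <- score[, t - 1] - penalty * (seq_len(3) != s)
      back[s, t] <- which.max(cand)
      score[s, t] <- max(cand) + states[s] * z[t]
    }
  }
  path <- integer(n)
  path[n] <- which.max(score[, n])
  for (t in seq.int(n - 1L, 1L)) path[t] <- back[path[t + 1L], t + 1L]
  states[path]
}

#' Call topological domains from a directionality-index track
#'
#' Segments the DI track into downstream-biased / none / upstream-biased
#' states by a penalized three-state dynamic program, then opens a domain
#' at each downstream-biased run and closes it at the end of the following
#' upstream-biased run. Deterministic for a given track.
#'
#' @param di data.table from [directionality_index()].
#' @param bins the `bin_scheme` the track lives on.
#' @param min_size minimum domain size in bp.
#' @param penalty state-change penalty of the segmentation, in robust
#'   z-units of the DI track.
#' @return data.table of domains (`chrom`, `start`, `end`).
#' @export
call_domains <- function(di, bins, min_size = 2e5, penalty = 10) {
  if (nrow(di) == 0L) stop("empty DI track")
  btab <- bins$bins[match(di$bin_id, bins$bins$bin_id)]
  if (all(di$di == 0))
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric()))
  st <- segment_di_states(di$di, penalty)
  runs <- rle(st)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  doms <- list()
  open_at <- NA_integer_
  for (r in seq_along(runs$values)) {
    if (runs$values[r] == 1) {
      open_at <- run_start[r]          # (re)open at a downstream-biased run
    } else if (runs$values[r] == -1 && !is.na(open_at)) {
      doms[[length(doms) + 1L]] <- c(open_at, run_end[r])
      open_at <- NA_integer_
    }
  }
  if (!length(doms))
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric()))
  dm <- data.table::data.table(
    chrom = btab$chrom[vapply(doms, `[`, 0, 1)],
    start = btab$start[vapply(doms, `[`, 0, 1)],
    end = btab$end[vapply(doms, `[`, 0, 2)])
  dm <- dm[end - start >= min_size]
  data.table::setorder(dm, chrom, start)
  dm[]
}

#' Gene-density orientation track for compartment calling
#'
#' Counts TSSs per bin of one chromosome; used to orient the sign of the
#' compartment eigenvector (gene-rich = A).
#'
#' @param expr expression table with `chrom` and `tss` columns.
#' @param bins a `bin_scheme`.
#' @param chrom chromosome.
#' @return numeric vector over the chromosome's bins.
#' @export
gene_density_track <- function(expr, bins, chrom) {
  bsel <- which(bins$bins$chrom == chrom)
  btab <- bins$bins[bsel]
  gsel <- which(expr$chrom == chrom)
  g <- expr[gsel]
  counts <- tabulate(findInterval(g$tss, btab$start), nbins = nrow(btab))
  counts
}
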