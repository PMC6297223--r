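# Binned contact matrices: pair filtering, binning, per-sample depth
# normalization, group means, and deletion-vs-control fold-change maps.

#' Construct a contact matrix
#'
#' Symmetric matrices are stored as the upper triangle of a COO table
#' (`bin1 <= bin2`), bound to a `bin_scheme`.
#'
#' @param entries data.table with `bin1`, `bin2`, `value` (and optionally
#'   `raw`); entries with `bin1 > bin2` are transposed in.
#' @param bins a `bin_scheme`.
#' @param normalization `"raw"` or `"depth_scaled"`.
#' @param total_raw_pairs total raw pair count behind the matrix.
#' @param sample_id identifier carried in metadata.
#' @export
contact_matrix <- function(entries, bins, normalization = "raw",
                           total_raw_pairs = NULL, sample_id = NA_character_) {
  e <- data.table::as.data.table(entries)
  stopifnot(all(c("bin1", "bin2", "value") %in% names(e)))
  swap <- e$bin1 > e$bin2
  if (any(swap)) {
    tmp <- e$bin1[swap]
    data.table::set(e, which(swap), "bin1", e$bin2[swap])
    data.table::set(e, which(swap), "bin2", tmp)
  }
  if (any(e$bin1 < 0 | e$bin2 >= bins$n_bins)) stop("bin id out of range")
  if (any(!is.finite(e$value)) || any(e$value < 0))
    stop("contact values must be finite and non-negative")
  keep <- c("bin1", "bin2", "value", intersect("raw", names(e)))
  e <- e[, keep, with = FALSE]
  e <- e[, lapply(.SD, sum), by = .(bin1, bin2)]
  data.table::setorder(e, bin1, bin2)
  if (is.null(total_raw_pairs)) total_raw_pairs <- sum(e$value)
  structure(list(bins = bins, entries = e, normalization = normalization,
                 total_raw_pairs = total_raw_pairs, sample_id = sample_id),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix [", x$normalization, "] ", nrow(x$entries),
      " cells, total mass ", format(sum(x$entries$value), digits = 6), "\n",
      sep = "")
  invisible(x)
}

#' Filter Hi-C read pairs
#'
#' Removes, in this order: exact duplicates (same chromosomes, positions and
#' strands on both ends), self-ligations (both ends on the same restriction
#' fragment of the same chromosome), and then either
#' * `standard` mode: pairs whose summed distances from the mapped positions
#'   to the nearest restriction sites exceed the library fragment length, or
#' * `haplotype` mode: pairs with either end farther than 1.5x the fragment
#'   length from a restriction site, or with an end-to-end span below 1.5x
#'   the fragment length on the same chromosome.
#'
#' @param pairs a `pair_table`.
#' @param model a `genome_model` (for fragment assignment).
#' @param library_fragment_length Hi-C library fragment length in bp.
#' @param mode `"standard"` or `"haplotype"`.
#' @return filtered `pair_table` with a `filter_report` attribute counting
#'   removals per category.
#' @export
filter_pairs <- function(pairs, model, library_fragment_length = 500,
                         mode = c("standard", "haplotype")) {
  mode <- match.arg(mode)
  dt <- pairs
  n_in <- nrow(dt)
  # all removal masks are computed on the input and applied in one subset,
  # so only one additional table of retained pairs is ever materialized
  dup <- duplicated(dt, by = c("chrom1", "pos1", "strand1",
                               "chrom2", "pos2", "strand2"))
  f1 <- integer(n_in); f2 <- integer(n_in)
  d1 <- numeric(n_in); d2 <- numeric(n_in)
  for (cn in unique(c(dt$chrom1, dt$chrom2))) {
    i1 <- which(dt$chrom1 == cn)
    a1 <- assign_to_fragment(model, cn, dt$pos1[i1])
    f1[i1] <- a1$frag_id; d1[i1] <- a1$dist
    i2 <- which(dt$chrom2 == cn)
    a2 <- assign_to_fragment(model, cn, dt$pos2[i2])
    f2[i2] <- a2$frag_id; d2[i2] <- a2$dist
  }
  selfl <- !dup & dt$chrom1 == dt$chrom2 & f1 == f2
  live <- !dup & !selfl
  if (mode == "standard") {
    drop_dist <- live & (d1 + d2) > library_fragment_length
    drop_span <- rep(FALSE, n_in)
  } else {
    drop_dist <- live & (d1 > 1.5 * library_fragment_length |
                           d2 > 1.5 * library_fragment_length)
    span <- ifelse(dt$chrom1 == dt$chrom2, dt$pos2 - dt$pos1, Inf)
    drop_span <- live & !drop_dist & span < 1.5 * library_fragment_length
  }
  keep <- live & !drop_dist & !drop_span
  out <- dt[keep]
  data.table::set(out, j = "frag1", value = f1[keep])
  data.table::set(out, j = "frag2", value = f2[keep])
  data.table::setattr(out, "class", class(pairs))
  data.table::setattr(out, "filter_report", list(
    input = n_in, duplicates = sum(dup), self_ligation = sum(selfl),
    restriction_distance = sum(drop_dist), short_span = sum(drop_span),
    retained = nrow(out), mode = mode))
  out[]
}

#' Bin read pairs into a raw contact matrix
#'
#' Every pair increments exactly one cell, so matrix mass equals the number
#' of pairs.
#'
#' @param pairs a `pair_table`.
#' @param bins a `bin_scheme`.
#' @param sample_id metadata tag.
#' @export
bin_pairs_to_matrix <- function(pairs, bins, sample_id = NA_character_) {
  b1 <- bin_id_of(bins, pairs$chrom1, pairs$pos1)
  b2 <- bin_id_of(bins, pairs$chrom2, pairs$pos2)
  e <- data.table::data.table(bin1 = pmin(b1, b2), bin2 = pmax(b1, b2))
  e <- e[, .(value = as.numeric(.N)), by = .(bin1, bin2)]
  contact_matrix(e, bins, "raw", total_raw_pairs = nrow(pairs),
                 sample_id = sample_id)
}

#' Scale a raw matrix to a target total depth
#'
#' Per-sample depth scaling before group combination: all values are
#' multiplied by `target_total / total_raw_pairs`. Raw counts are kept in a
#' `raw` column for downstream inclusion filters.
#'
#' @param cm a raw `contact_matrix`.
#' @param target_total target total mass (default 10 million pairs).
#' @export
depth_normalize <- function(cm, target_total = 1e7) {
  if (cm$normalization != "raw")
    stop("matrix is already normalized (", cm$normalization, ")")
  if (!is.finite(target_total) || target_total <= 0)
    stop("target_total must be positive")
  if (nrow(cm$entries) == 0L || cm$total_raw_pairs == 0) stop("empty matrix")
  e <- data.table::copy(cm$entries)
  e[, raw := value]
  e[, value := value * (target_total / cm$total_raw_pairs)]
  out <- contact_matrix(e, cm$bins, "depth_scaled",
                        total_raw_pairs = cm$total_raw_pairs,
                        sample_id = cm$sample_id)
  out
}

#' Element-wise mean of depth-scaled matrices
#'
#' Cells absent from a matrix count as zero.
#'
#' @param matrices list of depth-scaled `contact_matrix` objects on one
#'   bin scheme.
#' @export
combine_group <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  bins <- matrices[[1]]$bins
  norms <- vapply(matrices, function(m) m$normalization, "")
  if (length(unique(norms)) != 1L || norms[1] != "depth_scaled")
    stop("all matrices must be depth_scaled")
  for (m in matrices[-1]) if (!same_scheme(bins, m$bins))
    stop("bin scheme mismatch")
  all_e <- data.table::rbindlist(
    lapply(matrices, function(m) m$entries[, .(bin1, bin2, value)]))
  e <- all_e[, .(value = sum(value) / length(matrices)), by = .(bin1, bin2)]
  contact_matrix(e, bins, "depth_scaled",
                 total_raw_pairs = mean(vapply(matrices,
                                               function(m) m$total_raw_pairs, 0)),
                 sample_id = "group_mean")
}

#' Deletion-versus-control fold-change map
#'
#' Two contrasts of group-mean matrices are supported:
#' * `relative_log2` (default): `(log2(d+eps) - log2(c+eps)) / log2(c+eps)`,
#'   the relative change of log2-transformed mean contacts; cells whose
#'   denominator is not positive (`c + eps <= 1`) become `NaN` and are
#'   counted in the `n_undefined` attribute.
#' * `log2_ratio`: `log2((d+eps)/(c+eps))`.
#'
#' @param del_mean,ctrl_mean group-mean `contact_matrix` objects on one
#'   scheme.
#' @param mode `"relative_log2"` or `"log2_ratio"`.
#' @param eps pseudocount added to both group means.
#' @return data.table (`bin1`, `bin2`, `del`, `ctrl`, `fc`) with attributes
#'   `mode` and `n_undefined`.
#' @export
fold_change_map <- function(del_mean, ctrl_mean,
                            mode = c("relative_log2", "log2_ratio"), eps = 1) {
  mode <- match.arg(mode)
  if (!is.finite(eps) || eps <= 0) stop("eps must be positive")
  if (!same_scheme(del_mean$bins, ctrl_mean$bins)) stop("bin scheme mismatch")
  d <- del_mean$entries[, .(bin1, bin2, del = value)]
  c_ <- ctrl_mean$entries[, .(bin1, bin2, ctrl = value)]
  m <- merge(d, c_, by = c("bin1", "bin2"), all = TRUE)
  m[is.na(del), del := 0]; m[is.na(ctrl), ctrl := 0]
  if (mode == "log2_ratio") {
    m[, fc := log2((del + eps) / (ctrl + eps))]
    n_undef <- 0L
  } else {
    denom <- log2(m$ctrl + eps)
    m[, fc := ifelse(denom > 0, (log2(del + eps) - denom) / denom, NaN)]
    n_undef <- sum(denom <= 0)
  }
  data.table::setattr(m, "mode", mode)
  data.table::setattr(m, "n_undefined", n_undef)
  m[]
}

#' Rank 1-Mbp partner windows by contact fold change against an anchor
#'
#' Sums group-mean contacts over the rectangle anchor x partner for every
#' fixed-width partner window on the anchor's chromosome and ranks partners
#' by deletion/control fold change.
#'
#' @param del_mean,ctrl_mean group-mean `contact_matrix` objects.
#' @param anchor list or vector `(chrom, start, end)` of the anchor window.
#' @param partner_width partner window width in bp (default 1 Mbp).
#' @param eps pseudocount on summed contacts.
#' @param model optional `genome_model`; partners overlapping a deletion
#'   interval (either haplotype) are flagged.
#' @return data.table sorted by decreasing fold change with columns
#'   `partner_start`, `partner_end`, `del_sum`, `ctrl_sum`, `fold_change`,
#'   `overlaps_deletion`.
#' @export
cis_window_fold_change_ranking <- function(del_mean, ctrl_mean, anchor,
                                           partner_width = 1e6, eps = 1,
                                           model = NULL) {
  if (!same_scheme(del_mean$bins, ctrl_mean$bins)) stop("bin scheme mismatch")
  bins <- del_mean$bins
  chrom <- as.character(anchor[[1]])
  a_start <- as.numeric(anchor[[2]]); a_end <- as.numeric(anchor[[3]])
  L <- bins$chrom_lengths[[chrom]]
  if (is.null(L) || is.na(L)) stop("unknown anchor chromosome")
  if (a_start < 0 || a_end > L || a_start >= a_end)
    stop("anchor outside chromosome")
  bsel <- which(bins$bins$chrom == chrom)
  btab <- bins$bins[bsel]
  anchor_bins <- btab[start < a_end & end > a_start, bin_id]
  win_starts <- seq(0, L - 1, by = partner_width)
  win_of_bin <- function(id) {
    s <- btab$start[match(id, btab$bin_id)]
    findInterval(s, win_starts)
  }
  grab <- function(cm) {
    e <- cm$entries[bin1 %in% btab$bin_id & bin2 %in% btab$bin_id]
    e1 <- e[bin1 %in% anchor_bins, .(partner = bin2, value)]
    e2 <- e[bin2 %in% anchor_bins & !(bin1 %in% anchor_bins),
            .(partner = bin1, value)]
    both <- data.table::rbindlist(list(e1, e2))
    both[, win := win_of_bin(partner)]
    both[, .(s = sum(value)), by = win]
  }
  d <- grab(del_mean); c_ <- grab(ctrl_mean)
  out <- data.table::data.table(win = seq_along(win_starts),
                                partner_start = win_starts,
                                partner_end = pmin(win_starts + partner_width, L))
  out <- merge(out, d, by = "win", all.x = TRUE)
  data.table::setnames(out, "s", "del_sum")
  out <- merge(out, c_, by = "win", all.x = TRUE)
  data.table::setnames(out, "s", "ctrl_sum")
  out[is.na(del_sum), del_sum := 0]; out[is.na(ctrl_sum), ctrl_sum := 0]
  out[, fold_change := (del_sum + eps) / (ctrl_sum + eps)]
  out[, overlaps_deletion := FALSE]
  if (!is.null(model)) {
    dsel <- which(model$deletions$chrom == chrom)
    dels <- model$deletions[dsel]
    for (k in seq_len(nrow(dels)))
      out[partner_start < dels$end[k] & partner_end > dels$start[k],
          overlaps_deletion := TRUE]
  }
  data.table::setorder(out, -fold_change)
  out[, win := NULL]
  out[]
}
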