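# Haplotype-resolved Hi-C: assign read ends to homologous chromosomes via
# phased SNVs, resolve pair-level haplotypes, equalize SNV density across
# the deletion region, and build per-homolog contact maps.

#' Assign read ends to haplotypes from their SNV allele tags
#'
#' A read end is `H1` if every phased SNV it covers carries the H1 allele
#' (at least one SNV), `H2` symmetrically, `conflict` if the covered
#' alleles disagree or match neither haplotype. Ends covering no SNV are
#' `unknown` (such ends appear in the output only if listed in `all_ends`).
#'
#' @param tags data.table of allele observations (`read_id`, `end`,
#'   `chrom`, `pos`, `allele`).
#' @param variants phased-variant table of the individual.
#' @param all_ends optional data.table (`read_id`, `end`) enumerating every
#'   end to report; ends without tags come back as `unknown`.
#' @return data.table (`read_id`, `end`, `haplotype`, `n_snvs`).
#' @export
assign_read_haplotype <- function(tags, variants, all_ends = NULL) {
  t <- data.table::as.data.table(tags)
  v <- variants[, .(chrom, pos, hap1_allele, hap2_allele)]
  m <- merge(t, v, by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
  if (anyNA(m$hap1_allele)) stop("tag position not present in variant table")
  m[, h1 := allele == hap1_allele]
  m[, h2 := allele == hap2_allele]
  calls <- m[, .(n_snvs = .N, a1 = all(h1), a2 = all(h2),
                 any_bad = any(!h1 & !h2)),
             by = .(read_id, end)]
  calls[, haplotype := data.table::fifelse(
    any_bad | (!a1 & !a2), "conflict",
    data.table::fifelse(a1, "H1", "H2"))]
  out <- calls[, .(read_id, end, haplotype, n_snvs)]
  if (!is.null(all_ends)) {
    out <- merge(data.table::as.data.table(all_ends)[, .(read_id, end)],
                 out, by = c("read_id", "end"), all.x = TRUE)
    out[is.na(haplotype), `:=`(haplotype = "unknown", n_snvs = 0L)]
  }
  out[]
}

#' Resolve a pair-level haplotype from its two end assignments
#'
#' Concordant or half-informative pairs inherit the informative end's
#' haplotype; pairs with conflicting ends, cross-haplotype ends, or no
#' information are discarded, with discard reasons counted.
#'
#' @param hap1,hap2 character vectors of end assignments
#'   (`H1`/`H2`/`unknown`/`conflict`).
#' @return list with `haplotype` (`H1`/`H2`/`discard`) and `reasons`
#'   (named counts of discards).
#' @export
resolve_pair_haplotype <- function(hap1, hap2) {
  stopifnot(length(hap1) == length(hap2))
  out <- rep("discard", length(hap1))
  conflict <- hap1 == "conflict" | hap2 == "conflict"
  cross <- !conflict & ((hap1 == "H1" & hap2 == "H2") |
                          (hap1 == "H2" & hap2 == "H1"))
  none <- hap1 == "unknown" & hap2 == "unknown"
  ok <- !conflict & !cross & !none
  out[ok] <- ifelse(hap1[ok] %in% c("H1", "H2"), hap1[ok], hap2[ok])
  list(haplotype = out,
       reasons = c(conflict = sum(conflict), cross_haplotype = sum(cross),
                   no_information = sum(none)))
}

#' Attach pair-level haplotypes to a pair table
#'
#' Convenience wrapper: end-level assignment from allele tags, then
#' pair-level resolution. The returned table keeps all pairs; `hap1`/`hap2`
#' hold the end calls and `pair_hap` the resolved haplotype (or
#' `"discard"`).
#'
#' @param pairs a `pair_table`.
#' @param tags allele tags from [tag_reads_with_alleles()] or equivalent.
#' @param variants phased-variant table.
#' @param in_place add the columns to `pairs` by reference instead of
#'   copying (for very large pair sets).
#' @return the pair table with `hap1`, `hap2`, `pair_hap` columns and a
#'   `discard_reasons` attribute.
#' @export
assign_pairs_haplotype <- function(pairs, tags, variants, in_place = FALSE) {
  calls <- assign_read_haplotype(tags, variants)
  dt <- if (in_place) pairs else data.table::as.data.table(pairs)
  for (e in 1:2) {
    ce <- calls[calls$end == e]
    i <- match(dt$read_id, ce$read_id)
    col <- paste0("hap", e)
    data.table::set(dt, j = col,
                    value = ifelse(is.na(i), "unknown", ce$haplotype[i]))
  }
  res <- resolve_pair_haplotype(dt$hap1, dt$hap2)
  dt[, pair_hap := res$haplotype]
  data.table::setattr(dt, "class", class(pairs))
  data.table::setattr(dt, "discard_reasons", res$reasons)
  dt[]
}

#' Equalize SNV density across a region by position sampling
#'
#' The expected number of phased heterozygous SNVs in the region is
#' computed from the density on the rest of the chromosome
#' (`round(region_length * density)` with
#' `density = n_outside / (chrom_length - region_length)`), and that many
#' distinct single-bp positions are drawn uniformly in the region, in each
#' of `n_samplings` replicates.
#'
#' @param variants phased-variant table.
#' @param model a `genome_model`.
#' @param region list or vector `(chrom, start, end)`.
#' @param n_samplings number of replicate draws (default 10).
#' @param seed integer seed.
#' @return list with `expected` (count), `density` (per bp), and
#'   `replicates` (list of sorted position vectors).
#' @export
equalize_snv_density <- function(variants, model, region, n_samplings = 10,
                                 seed = 1) {
  chrom <- as.character(region[[1]])
  r_start <- as.numeric(region[[2]]); r_end <- as.numeric(region[[3]])
  L <- chrom_length(model, chrom)
  if (r_start < 0 || r_end > L || r_start >= r_end)
    stop("region outside chromosome")
  r_len <- r_end - r_start
  if (r_len >= L) stop("region covers the whole chromosome; no density basis")
  sel <- which(variants$chrom == chrom)
  v <- variants[sel]
  n_out <- sum(v$pos < r_start | v$pos >= r_end)
  if (n_out == 0L) stop("no phased SNVs outside the region")
  density <- n_out / (L - r_len)
  expected <- round(r_len * density)
  if (expected > r_len) stop("expected count exceeds region length")
  set.seed(seed)
  reps <- lapply(seq_len(n_samplings), function(k)
    sort(sample.int(r_len, expected)) - 1 + r_start)
  list(expected = expected, density = density, replicates = reps,
       region = list(chrom = chrom, start = r_start, end = r_end))
}

# does a read starting at pos (covering read_length bp) overlap any sampled
# position? `sampled` must be sorted.
covers_sampled <- function(pos, sampled, read_length) {
  findInterval(pos + read_length - 0.5, sampled) -
    findInterval(pos - 0.5, sampled) > 0
}

#' Build per-homolog contact matrices
#'
#' Bins haplotype-resolved pairs separately for H1 and H2. When an
#' equalization region is configured, contacts with an endpoint inside the
#' region are kept only if at least one region endpoint's read overlaps one
#' of the sampled positions, applied to both homologs alike; one matrix set
#' is produced per sampling replicate, plus the mean across replicates.
#'
#' @param pairs pair table with a `pair_hap` column (from
#'   [assign_pairs_haplotype()]), already filtered in haplotype mode.
#' @param bins a `bin_scheme`.
#' @param equalization optional result of [equalize_snv_density()].
#' @param read_length read length in bp for the overlap rule.
#' @return list with `replicates` (list of `list(H1=, H2=)` contact
#'   matrices), `mean` (`list(H1=, H2=)` mean matrices), and `n_assigned`.
#' @export
build_haplotype_matrix <- function(pairs, bins, equalization = NULL,
                                   read_length = 101L) {
  dt <- data.table::as.data.table(pairs)
  if (!"pair_hap" %in% names(dt)) stop("pairs lack pair-level haplotypes")
  dt <- dt[pair_hap %in% c("H1", "H2")]
  one_set <- function(sub, tag) {
    lapply(stats::setNames(nm = c("H1", "H2")), function(h) {
      bin_pairs_to_matrix(sub[sub$pair_hap == h], bins,
                          sample_id = paste0(tag, "_", h))
    })
  }
  if (is.null(equalization)) {
    m <- one_set(dt, "all")
    return(list(replicates = list(m), mean = m, n_assigned = nrow(dt)))
  }
  reg <- equalization$region
  in_reg1 <- dt$chrom1 == reg$chrom & dt$pos1 >= reg$start & dt$pos1 < reg$end
  in_reg2 <- dt$chrom2 == reg$chrom & dt$pos2 >= reg$start & dt$pos2 < reg$end
  reps <- lapply(seq_along(equalization$replicates), function(k) {
    s <- equalization$replicates[[k]]
    hit1 <- in_reg1 & covers_sampled(dt$pos1, s, read_length)
    hit2 <- in_reg2 & covers_sampled(dt$pos2, s, read_length)
    keep <- (!in_reg1 & !in_reg2) | hit1 | hit2
    one_set(dt[keep], paste0("rep", k))
  })
  mean_set <- lapply(stats::setNames(nm = c("H1", "H2")), function(h)
    combine_raw_mean(lapply(reps, `[[`, h)))
  list(replicates = reps, mean = mean_set, n_assigned = nrow(dt))
}

# element-wise mean of raw matrices (used for sampling replicates)
combine_raw_mean <- function(matrices) {
  bins <- matrices[[1]]$bins
  e <- data.table::rbindlist(lapply(matrices, function(m)
    m$entries[, .(bin1, bin2, value)]))
  e <- e[, .(value = sum(value) / length(matrices)), by = .(bin1, bin2)]
  contact_matrix(e, bins, "raw",
                 total_raw_pairs = mean(vapply(matrices,
                                               function(m) m$total_raw_pairs, 0)),
                 sample_id = "replicate_mean")
}

#' Signed difference map between the two homologs
#'
#' Scales both homolog matrices to the mean of their assigned-pair totals,
#' then returns deleted-minus-intact (H1 minus H2 by default) per cell.
#'
#' @param h_del,h_intact `contact_matrix` objects of the two homologs on
#'   one bin scheme.
#' @param scale_equal scale both matrices to a common total first.
#' @return data.table (`bin1`, `bin2`, `del`, `intact`, `diff`) with a
#'   `scaling` attribute.
#' @export
haplotype_difference_map <- function(h_del, h_intact, scale_equal = TRUE) {
  if (!same_scheme(h_del$bins, h_intact$bins)) stop("bin scheme mismatch")
  t1 <- sum(h_del$entries$value); t2 <- sum(h_intact$entries$value)
  target <- (t1 + t2) / 2
  f1 <- if (scale_equal) target / t1 else 1
  f2 <- if (scale_equal) target / t2 else 1
  a <- h_del$entries[, .(bin1, bin2, del = value * f1)]
  b <- h_intact$entries[, .(bin1, bin2, intact = value * f2)]
  m <- merge(a, b, by = c("bin1", "bin2"), all = TRUE)
  m[is.na(del), del := 0]; m[is.na(intact), intact := 0]
  m[, diff := del - intact]
  data.table::setattr(m, "scaling", c(del = f1, intact = f2))
  m[]
}

#' Flag candidate phasing switch points
#'
#' For every window boundary, considers the cis pairs with both ends
#' haplotype-informative that span the boundary: intra-chromosomal contacts
#' should be predominantly intra-homolog, so boundaries where
#' cross-haplotype spanning pairs outnumber concordant ones are flagged as
#' candidate phase switches. Report only; no correction is applied.
#'
#' @param pairs pair table with end-level `hap1`/`hap2` calls (cis pairs
#'   are used).
#' @param model a `genome_model`.
#' @param window boundary spacing in bp; the reported interval extends one
#'   half-window either side of the flagged boundaries.
#' @return data.table of flagged intervals (`chrom`, `start`, `end`,
#'   `n_cross`, `n_concordant`), adjacent flagged boundaries merged.
#' @export
detect_phasing_switches <- function(pairs, model, window = 1e6) {
  empty <- data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), n_cross = integer(),
                                  n_concordant = integer())
  dt <- data.table::as.data.table(pairs)
  dt <- dt[chrom1 == chrom2]
  informative <- dt$hap1 %in% c("H1", "H2") & dt$hap2 %in% c("H1", "H2")
  dt <- dt[informative]
  if (nrow(dt) == 0L) return(empty)
  dt[, cross := hap1 != hap2]
  # expand each pair to the window boundaries it spans
  b1 <- dt$pos1 %/% window
  b2 <- dt$pos2 %/% window
  n_span <- pmax(b2 - b1, 0)
  has <- which(n_span > 0)
  if (!length(has)) return(empty)
  bidx <- sequence(n_span[has]) + rep.int(b1[has], n_span[has])
  stat <- data.table::data.table(
    chrom = rep.int(dt$chrom1[has], n_span[has]),
    boundary = bidx,
    cross = rep.int(dt$cross[has], n_span[has]))
  stat <- stat[, .(n_cross = sum(cross), n_concordant = sum(!cross)),
               by = .(chrom, boundary)]
  flagged <- stat[n_cross > n_concordant]
  if (nrow(flagged) == 0L) return(empty)
  data.table::setorder(flagged, chrom, boundary)
  flagged[, grp := cumsum(c(1L, diff(boundary) != 1L |
                              chrom[-1] != chrom[-.N]))]
  out <- flagged[, .(start = min(boundary) * window - window / 2,
                     end = max(boundary) * window + window / 2,
                     n_cross = sum(n_cross),
                     n_concordant = sum(n_concordant)),
                 by = .(chrom, grp)]
  out[, start := pmax(start, 0)]
  out[, end := pmin(end, chrom_length(model, chrom)), by = chrom]
  out[, grp := NULL]
  out[]
}
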