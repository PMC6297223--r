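# Genome model: chromosomes, haplotype-specific deletion intervals, and a
# restriction-fragment map. All in-memory coordinates are 0-based half-open;
# on-disk formats (.pairs, variant files) are 1-based and converted at I/O.

#' Build a genome model
#'
#' The genome model is the single source of coordinate truth for the whole
#' pipeline: chromosome names and lengths, per-haplotype deletion intervals
#' (on the reference frame), and a restriction-fragment cut map.
#'
#' Deletions are genotype-level intervals: a sample carrying the deletion has
#' the interval removed from the stated haplotype, a control sample has none.
#' Which samples carry it is decided by the cohort configuration, not here.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp, or a
#'   data.frame with columns `name` and `length`.
#' @param deletions `NULL`, or a data.frame with columns `chrom`, `start`,
#'   `end`, `haplotype` (one of `"H1"`, `"H2"`); 0-based half-open reference
#'   coordinates.
#' @param cut_spacing spacing in bp of regularly placed restriction cuts,
#'   used when `fragment_cuts` is not given. The default 400 bp emulates a
#'   4-bp cutter.
#' @param fragment_cuts optional named list (per chromosome) of explicit,
#'   strictly increasing internal cut positions in bp.
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, deletions = NULL, cut_spacing = 400,
                         fragment_cuts = NULL) {
  if (is.data.frame(chromosomes)) {
    chroms <- data.table::data.table(name = as.character(chromosomes$name),
                                     length = as.numeric(chromosomes$length))
  } else {
    if (is.null(names(chromosomes)) || any(names(chromosomes) == ""))
      stop("chromosomes must be named")
    chroms <- data.table::data.table(name = names(chromosomes),
                                     length = as.numeric(chromosomes))
  }
  if (anyDuplicated(chroms$name)) stop("duplicate chromosome names")
  if (any(!is.finite(chroms$length)) || any(chroms$length <= 0))
    stop("chromosome lengths must be positive")

  if (is.null(deletions)) {
    dels <- data.table::data.table(chrom = character(), start = numeric(),
                                   end = numeric(), haplotype = character())
  } else {
    dels <- data.table::as.data.table(deletions)[
      , .(chrom = as.character(chrom), start = as.numeric(start),
          end = as.numeric(end), haplotype = as.character(haplotype))]
    if (any(!dels$haplotype %in% c("H1", "H2")))
      stop("deletion haplotype must be 'H1' or 'H2'")
    if (any(!dels$chrom %in% chroms$name))
      stop("deletion on unknown chromosome")
    len <- chroms$length[match(dels$chrom, chroms$name)]
    if (any(dels$start < 0) || any(dels$end > len) || any(dels$start >= dels$end))
      stop("deletion interval outside chromosome or empty")
    data.table::setorder(dels, haplotype, chrom, start)
    # non-overlap per haplotype+chromosome
    ov <- dels[, any(start[-1] < end[-.N]), by = .(haplotype, chrom)]
    if (nrow(ov) && any(ov$V1)) stop("overlapping deletions on one haplotype")
  }

  if (is.null(fragment_cuts)) {
    if (!is.finite(cut_spacing) || cut_spacing <= 0)
      stop("cut_spacing must be positive")
    fragment_cuts <- lapply(seq_len(nrow(chroms)), function(i) {
      L <- chroms$length[i]
      if (L <= cut_spacing) numeric(0) else seq(cut_spacing, L - 1, by = cut_spacing)
    })
    names(fragment_cuts) <- chroms$name
  } else {
    if (!all(chroms$name %in% names(fragment_cuts)))
      stop("fragment_cuts must cover every chromosome")
    for (nm in chroms$name) {
      cuts <- fragment_cuts[[nm]]
      if (length(cuts) && (is.unsorted(cuts, strictly = TRUE) ||
                           cuts[1] <= 0 ||
                           cuts[length(cuts)] >= chroms$length[chroms$name == nm]))
        stop("fragment cuts must be strictly increasing and internal: ", nm)
    }
    fragment_cuts <- fragment_cuts[chroms$name]
  }

  structure(list(chromosomes = chroms, deletions = dels,
                 fragment_map = fragment_cuts),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$deletions), "deletion interval(s)\n")
  invisible(x)
}

chrom_length <- function(model, chrom) {
  i <- match(chrom, model$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ","))
  model$chromosomes$length[i]
}

#' Deletion intervals for one haplotype and chromosome
#'
#' @param model a `genome_model`.
#' @param haplotype `"H1"` or `"H2"`.
#' @param chrom chromosome name.
#' @return data.table of intervals (possibly empty), sorted by start.
#' @export
haplotype_deletions <- function(model, haplotype, chrom) {
  if (!haplotype %in% c("H1", "H2")) stop("unknown haplotype id: ", haplotype)
  d <- model$deletions
  sel <- which(d$haplotype == haplotype & d$chrom == chrom)
  d[sel, ]
}

#' Length of a chromosome on one haplotype (reference length minus deletions)
#' @inheritParams haplotype_deletions
#' @export
haplotype_chrom_length <- function(model, haplotype, chrom) {
  d <- haplotype_deletions(model, haplotype, chrom)
  chrom_length(model, chrom) - sum(d$end - d$start)
}

#' Map reference positions to haplotype-frame positions
#'
#' Positions left of every deletion are unchanged; positions right of a
#' deletion shift left by the deleted length; positions inside a deletion
#' map to `NA` (that DNA does not exist on the haplotype).
#'
#' @inheritParams haplotype_deletions
#' @param pos numeric vector of 0-based reference positions.
#' @return numeric vector of haplotype-frame positions, `NA` inside deletions.
#' @export
map_reference_to_haplotype <- function(model, haplotype, chrom, pos) {
  L <- chrom_length(model, chrom)
  if (any(pos < 0 | pos >= L)) stop("position outside chromosome")
  d <- haplotype_deletions(model, haplotype, chrom)
  if (nrow(d) == 0L) return(pos)
  out <- pos
  shift <- numeric(length(pos))
  for (k in seq_len(nrow(d))) {
    inside <- pos >= d$start[k] & pos < d$end[k]
    out[inside] <- NA_real_
    shift <- shift + (pos >= d$end[k]) * (d$end[k] - d$start[k])
  }
  ifelse(is.na(out), NA_real_, out - shift)
}

#' Map haplotype-frame positions back to the reference frame
#'
#' Inverse of [map_reference_to_haplotype()] on non-deleted positions.
#'
#' @inheritParams haplotype_deletions
#' @param pos numeric vector of 0-based haplotype-frame positions.
#' @export
map_haplotype_to_reference <- function(model, haplotype, chrom, pos) {
  hl <- haplotype_chrom_length(model, haplotype, chrom)
  if (any(pos < 0 | pos >= hl)) stop("position outside haplotype chromosome")
  d <- haplotype_deletions(model, haplotype, chrom)
  if (nrow(d) == 0L) return(pos)
  out <- pos
  # deletion starts expressed in the haplotype frame, in order
  off <- 0
  for (k in seq_len(nrow(d))) {
    hstart <- d$start[k] - off
    out <- out + (pos >= hstart) * (d$end[k] - d$start[k])
    off <- off + (d$end[k] - d$start[k])
  }
  out
}

#' Assign positions to restriction fragments
#'
#' Fragment ids count cuts at or before the position, so a position exactly
#' at a cut belongs to the right-hand fragment. The reported distance is to
#' the nearest flanking cut, with the chromosome ends counting as cuts.
#'
#' @param model a `genome_model`.
#' @param chrom chromosome name (scalar).
#' @param pos numeric vector of 0-based positions.
#' @return data.table with columns `frag_id` and `dist` (bp).
#' @export
assign_to_fragment <- function(model, chrom, pos) {
  L <- chrom_length(model, chrom)
  if (any(pos < 0 | pos >= L)) stop("position outside chromosome")
  cuts <- model$fragment_map[[chrom]]
  frag <- findInterval(pos, cuts)
  bounds <- c(0, cuts, L)
  left <- bounds[frag + 1L]
  right <- bounds[frag + 2L]
  data.table::data.table(frag_id = frag, dist = pmin(pos - left, right - pos))
}

#' Tile a genome into fixed-width bins
#'
#' @param model a `genome_model`.
#' @param resolution bin width in bp.
#' @return an object of class `bin_scheme` with a dense 0-based `bin_id`
#'   across chromosomes in model order; the last bin of a chromosome may be
#'   short.
#' @export
make_bins <- function(model, resolution) {
  if (!is.finite(resolution) || resolution <= 0) stop("resolution must be positive")
  resolution <- as.numeric(resolution)
  pieces <- lapply(seq_len(nrow(model$chromosomes)), function(i) {
    nm <- model$chromosomes$name[i]
    L <- model$chromosomes$length[i]
    n <- ceiling(L / resolution)
    start <- (seq_len(n) - 1) * resolution
    data.table::data.table(chrom = nm, start = start,
                           end = pmin(start + resolution, L))
  })
  bins <- data.table::rbindlist(pieces)
  bins[, bin_id := seq_len(.N) - 1L]
  data.table::setcolorder(bins, c("bin_id", "chrom", "start", "end"))
  offsets <- c(0L, cumsum(vapply(pieces, nrow, integer(1))))
  names(offsets) <- c(model$chromosomes$name, "..end")
  structure(list(resolution = resolution, bins = bins,
                 offsets = offsets[seq_len(nrow(model$chromosomes))],
                 n_bins = nrow(bins),
                 chrom_lengths = stats::setNames(model$chromosomes$length,
                                                 model$chromosomes$name)),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat("bin_scheme:", x$n_bins, "bins at", format(x$resolution, big.mark = ","),
      "bp\n")
  invisible(x)
}

#' Map positions to bin ids
#' @param bins a `bin_scheme`.
#' @param chrom character vector of chromosome names.
#' @param pos numeric vector of 0-based positions.
#' @return integer vector of bin ids.
#' @export
bin_id_of <- function(bins, chrom, pos) {
  off <- bins$offsets[chrom]
  if (anyNA(off)) stop("unknown chromosome in bin lookup")
  L <- bins$chrom_lengths[chrom]
  if (any(pos < 0 | pos >= L)) stop("position outside chromosome")
  as.integer(off + pos %/% bins$resolution)
}

same_scheme <- function(a, b) {
  a$resolution == b$resolution && a$n_bins == b$n_bins &&
    identical(a$offsets, b$offsets)
}
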