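# Readers/writers for the on-disk formats. All files are plain TAB text.
# Positions are 1-based on disk (as in .pairs and VCF) and 0-based in memory.

PAIR_COLS <- c("read_id", "chrom1", "pos1", "chrom2", "pos2",
               "strand1", "strand2")
PAIR_COLS_EXT <- c(PAIR_COLS, "frag1", "frag2", "hap1", "hap2")
HAP_LEVELS <- c("H1", "H2", "unknown", "conflict")

hap_to_disk <- function(h) c(H1 = "H1", H2 = "H2", unknown = ".", conflict = "!")[h]
hap_from_disk <- function(h) {
  out <- rep(NA_character_, length(h))
  out[h == "H1"] <- "H1"; out[h == "H2"] <- "H2"
  out[h == "."] <- "unknown"; out[h == "!"] <- "conflict"
  if (anyNA(out)) stop("invalid haplotype tag on disk: ",
                       paste(unique(h[is.na(out)]), collapse = ","))
  out
}

#' Construct a pair table
#'
#' Normalizes a data.frame of read-pair records into the canonical in-memory
#' form: 0-based positions and mates ordered so that (chrom1, pos1) <=
#' (chrom2, pos2) in genome order.
#'
#' @param df data.frame with at least `read_id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `strand1`, `strand2`; optionally `frag1`, `frag2`, `hap1`,
#'   `hap2`.
#' @param model optional `genome_model` used for chromosome validation and
#'   mate ordering; without it chromosomes are ordered alphabetically.
#' @return a `data.table` of class `pair_table`.
#' @export
pair_table <- function(df, model = NULL) {
  # a data.table input is taken over without copying (large pair sets)
  dt <- if (data.table::is.data.table(df)) df else data.table::as.data.table(df)
  for (col in setdiff(PAIR_COLS_EXT, names(dt))) {
    dt[, (col) := if (col %in% c("frag1", "frag2")) NA_integer_
                  else if (col %in% c("hap1", "hap2")) "unknown"
                  else stop("pair table missing column: ", col)]
  }
  if (!is.null(model)) {
    chrom_order <- model$chromosomes$name
    bad <- setdiff(unique(c(dt$chrom1, dt$chrom2)), chrom_order)
    if (length(bad)) stop("unknown chromosome: ", paste(bad, collapse = ","))
    L1 <- chrom_length(model, dt$chrom1); L2 <- chrom_length(model, dt$chrom2)
    if (any(dt$pos1 < 0 | dt$pos1 >= L1) || any(dt$pos2 < 0 | dt$pos2 >= L2))
      stop("pair position outside chromosome")
    r1 <- match(dt$chrom1, chrom_order); r2 <- match(dt$chrom2, chrom_order)
  } else {
    r1 <- dt$chrom1; r2 <- dt$chrom2
  }
  swap <- r2 < r1 | (r1 == r2 & dt$pos2 < dt$pos1)
  if (any(swap)) {
    for (pair in list(c("chrom1", "chrom2"), c("pos1", "pos2"),
                      c("strand1", "strand2"), c("frag1", "frag2"),
                      c("hap1", "hap2"))) {
      a <- dt[[pair[1]]][swap]
      data.table::set(dt, which(swap), pair[1], dt[[pair[2]]][swap])
      data.table::set(dt, which(swap), pair[2], a)
    }
  }
  data.table::setcolorder(dt, PAIR_COLS_EXT)
  data.table::setattr(dt, "class", c("pair_table", class(data.table::data.table())))
  dt[]
}

#' Write a pair table in the .pairs-style dialect
#'
#' Columns: readID chr1 pos1 chr2 pos2 strand1 strand2 frag1 frag2 hap1 hap2,
#' TAB separated, positions 1-based, haplotype tags H1/H2/./!.
#'
#' @param pairs a `pair_table`.
#' @param path output file.
#' @export
write_pairs <- function(pairs, path) {
  out <- data.table::as.data.table(pairs)
  out <- out[, .(read_id, chrom1, pos1 = pos1 + 1, chrom2, pos2 = pos2 + 1,
                 strand1, strand2,
                 frag1 = ifelse(is.na(frag1), ".", as.character(frag1)),
                 frag2 = ifelse(is.na(frag2), ".", as.character(frag2)),
                 hap1 = hap_to_disk(hap1), hap2 = hap_to_disk(hap2))]
  writeLines(c("## pairs-dialect v1",
               paste0("#columns: readID chr1 pos1 chr2 pos2 strand1 strand2",
                      " frag1 frag2 hap1 hap2")), path)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a .pairs-style file
#'
#' @param path input file; header lines start with `#`.
#' @param model optional `genome_model` for validation.
#' @return a `pair_table`.
#' @export
read_pairs <- function(path, model = NULL) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  body_idx <- which(!is_header)
  if (length(body_idx) == 0L)
    return(pair_table(data.table::data.table(
      read_id = character(), chrom1 = character(), pos1 = numeric(),
      chrom2 = character(), pos2 = numeric(),
      strand1 = character(), strand2 = character()), model))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(!(nf %in% c(7L, 11L)))
  if (length(bad))
    stop("malformed pair line ", body_idx[bad[1]], ": expected 7 or 11 columns, got ",
         nf[bad[1]])
  if (length(unique(nf)) > 1L)
    stop("mixed column counts in pair file (first odd line ",
         body_idx[which(nf != nf[1])[1]], ")")
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  p1 <- suppressWarnings(as.numeric(m[, 3])); p2 <- suppressWarnings(as.numeric(m[, 5]))
  badp <- which(is.na(p1) | is.na(p2) | p1 != floor(p1) | p2 != floor(p2))
  if (length(badp))
    stop("non-integer position at line ", body_idx[badp[1]])
  dt <- data.table::data.table(
    read_id = m[, 1], chrom1 = m[, 2], pos1 = p1 - 1,
    chrom2 = m[, 4], pos2 = p2 - 1, strand1 = m[, 6], strand2 = m[, 7])
  if (nf[1] == 11L) {
    dt[, frag1 := ifelse(m[, 8] == ".", NA_integer_, as.integer(m[, 8]))]
    dt[, frag2 := ifelse(m[, 9] == ".", NA_integer_, as.integer(m[, 9]))]
    dt[, hap1 := hap_from_disk(m[, 10])]
    dt[, hap2 := hap_from_disk(m[, 11])]
  }
  pair_table(dt, model)
}

#' Read phased heterozygous variants from a VCF-like file
#'
#' Keeps only phased heterozygous records (GT like `0|1`); homozygous and
#' unphased records are counted and skipped with a message. Positions are
#' converted to 0-based.
#'
#' @param path VCF-like TAB text with columns CHROM POS ID REF ALT QUAL
#'   FILTER INFO FORMAT SAMPLE and GT first in FORMAT.
#' @return data.table with columns `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `hap1_allele`, `hap2_allele`; attribute `skipped` holds
#'   the skip counters.
#' @export
read_phased_variants <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- data.table::data.table(chrom = character(), pos = numeric(),
                                  ref_allele = character(), alt_allele = character(),
                                  hap1_allele = character(), hap2_allele = character())
  if (length(body) == 0L) return(empty)
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 10L))
    stop("missing genotype column at line ",
         which(lengths(fields) < 10L)[1])
  m <- matrix(unlist(lapply(fields, `[`, 1:10)), ncol = 10, byrow = TRUE)
  fmt1 <- vapply(strsplit(m[, 9], ":", fixed = TRUE), `[`, "", 1)
  if (any(fmt1 != "GT")) stop("FORMAT must list GT first")
  gt <- vapply(strsplit(m[, 10], ":", fixed = TRUE), `[`, "", 1)
  phased <- grepl("^[01]\\|[01]$", gt)
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  het <- phased & a1 != a2
  n_unphased <- sum(!phased)
  n_hom <- sum(phased & !het)
  if (n_unphased + n_hom > 0)
    message("read_phased_variants: skipped ", n_unphased, " unphased and ",
            n_hom, " homozygous record(s)")
  if (!any(het)) {
    out <- empty
  } else {
    ref <- m[het, 4]; alt <- m[het, 5]
    out <- data.table::data.table(
      chrom = m[het, 1], pos = as.numeric(m[het, 2]) - 1,
      ref_allele = ref, alt_allele = alt,
      hap1_allele = ifelse(a1[het] == "0", ref, alt),
      hap2_allele = ifelse(a2[het] == "0", ref, alt))
    data.table::setorder(out, chrom, pos)
    if (any(out[, duplicated(pos), by = chrom]$V1))
      stop("duplicate variant positions on a chromosome")
  }
  data.table::setattr(out, "skipped",
                      c(unphased = n_unphased, homozygous = n_hom))
  out
}

#' Write phased heterozygous variants in the VCF-like dialect
#' @param variants data.table as returned by [read_phased_variants()].
#' @param path output file.
#' @param sample_id sample column name.
#' @export
write_phased_variants <- function(variants, path, sample_id = "SAMPLE") {
  gt <- ifelse(variants$hap1_allele == variants$ref_allele, "0|1", "1|0")
  out <- data.table::data.table(
    CHROM = variants$chrom, POS = variants$pos + 1, ID = ".",
    REF = variants$ref_allele, ALT = variants$alt_allele,
    QUAL = ".", FILTER = "PASS", INFO = ".", FORMAT = "GT", S = gt)
  data.table::setnames(out, "S", sample_id)
  writeLines(c("##fileformat=VCFv4.2-like",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample_id)), path)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a BED file into an interval set
#'
#' BED is 0-based half-open on disk, which matches the in-memory convention,
#' so coordinates pass through unchanged.
#'
#' @param path BED file (3 or 4 columns).
#' @return data.table with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns")
  out <- data.table::data.table(chrom = as.character(dt[[1]]),
                                start = as.numeric(dt[[2]]),
                                end = as.numeric(dt[[3]]),
                                name = if (ncol(dt) >= 4L) as.character(dt[[4]])
                                       else rep(".", nrow(dt)))
  if (any(out$start >= out$end)) stop("BED interval with start >= end")
  if (any(out$start < 0)) stop("negative BED coordinate")
  out
}

#' Write a bedGraph track
#'
#' Values are serialized to 6 significant digits.
#'
#' @param track data.table with `chrom`, `start`, `end`, `value`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  if (any(!is.finite(track$value))) stop("track values must be finite")
  out <- data.table::data.table(track$chrom, track$start, track$end,
                                formatC(signif(track$value, 6), format = "g",
                                        digits = 6))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#' @param path bedGraph file.
#' @return data.table with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  dt[, `:=`(chrom = as.character(chrom), start = as.numeric(start),
            end = as.numeric(end), value = as.numeric(value))]
  dt[]
}

#' Write a contact matrix as bins + COO TSV
#' @param cm a `contact_matrix`.
#' @param bins_path,coo_path output files.
#' @export
write_matrix <- function(cm, bins_path, coo_path) {
  writeLines(paste0("# resolution=",
                    format(cm$bins$resolution, scientific = FALSE)), bins_path)
  data.table::fwrite(cm$bins$bins, bins_path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  writeLines(c(paste0("# normalization=", cm$normalization),
               paste0("# total_raw_pairs=",
                      format(cm$total_raw_pairs, scientific = FALSE))),
             coo_path)
  data.table::fwrite(cm$entries, coo_path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(coo_path)
}
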