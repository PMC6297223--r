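# Shared fixtures. Heavy simulated objects are built once per test run and
# cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small diploid genome: one 10-Mbp chromosome with a 2-Mbp deletion on H1,
# plus a 4-Mbp decoy
tiny_model <- function() {
  genome_model(c(chrA = 10e6, chrB = 4e6),
               deletions = data.frame(chrom = "chrA", start = 5e6, end = 7e6,
                                      haplotype = "H1"))
}

tiny_config <- function(seed = 1, ...) {
  cohort_config(
    seed = seed,
    genome = tiny_model(),
    n_genes = 300L, ase_n_snvs = 400L,
    n_peaks_background = c(H3K27ac = 250, H3K27me3 = 200, CTCF = 250),
    flank_regions = data.frame(chrom = "chrA",
                               start = c(4e6, 7e6), end = c(5e6, 8e6)),
    ctcf_corr_windows = data.frame(chrom = "chrA",
                                   start = c(1e6, 8e6), end = c(1.5e6, 8.5e6)),
    hotspots = data.frame(chrom1 = "chrA", start1 = 3e6, end1 = 3.5e6,
                          chrom2 = "chrB", start2 = 1e6, end2 = 1.5e6,
                          baseline = 4, multiplier = 3),
    ...)
}

# the default-condition cohort (5 del / 6 ctrl, 50-Mbp chromosome, 3-Mbp
# deletion) used by the acceptance-level checks. Built once, together with
# its depth-scaled 500-kbp matrices; the bulk read-pair tables are then
# dropped for all but the first sample of each group to keep the test-run
# footprint small.
default_bundle <- function() {
  cached("default_bundle", function() {
    co <- simulate_cohort(cohort_config(seed = 42))
    cfg <- co$config
    bins <- make_bins(cfg$genome, 5e5)
    mats <- lapply(names(co$samples), function(sid) {
      flt <- filter_pairs(co$samples[[sid]]$pairs, cfg$genome,
                          cfg$library_fragment_length, "standard")
      depth_normalize(bin_pairs_to_matrix(flt, bins, sid), cfg$depth_target)
    })
    names(mats) <- names(co$samples)
    keep <- c(names(co$statuses)[co$statuses == "del"][1],
              names(co$statuses)[co$statuses == "ctrl"][1])
    for (sid in setdiff(names(co$samples), keep)) {
      co$samples[[sid]]$pairs <- NULL
      co$samples[[sid]]$tags <- NULL
    }
    gc()
    list(cohort = co, matrices = mats)
  })
}

default_cohort <- function() default_bundle()$cohort

default_matrices <- function() default_bundle()$matrices

default_group_means <- function() {
  cached("default_means", function() {
    co <- default_cohort()
    mats <- default_matrices()
    list(del = combine_group(mats[co$statuses == "del"]),
         ctrl = combine_group(mats[co$statuses == "ctrl"]),
         bins = mats[[1]]$bins)
  })
}

# capture-style patient: a single deletion sample sequenced deeply over the
# target chromosome only (the homolog-map analyses use capture Hi-C), with
# haplotype assignment and SNV-density equalization already run
capture_patient <- function() {
  cached("capture_patient", function() {
    gm <- genome_model(c(chr22s = 50e6),
                       deletions = data.frame(chrom = "chr22s", start = 18.5e6,
                                              end = 21.5e6, haplotype = "H1"))
    cfg <- cohort_config(seed = 42, genome = gm, cis_scale = 150,
                         hotspots = data.frame())
    set.seed(1042)
    p <- simulate_sample_pairs(cfg, "del", "pt1")
    v <- simulate_phased_snvs(cfg)
    flt <- filter_pairs(p, cfg$genome, cfg$library_fragment_length,
                        "haplotype")
    rm(p); gc()
    tg <- tag_reads_with_alleles(flt, v)
    hp <- assign_pairs_haplotype(flt, tg, v, in_place = TRUE)
    rm(flt, tg)
    informative <- hp[hp$pair_hap %in% c("H1", "H2"), ]
    stats <- list(
      accuracy = mean(informative$pair_hap == informative$true_hap),
      n_informative = nrow(informative),
      n_conflicts = sum(hp$hap1 == "conflict" | hp$hap2 == "conflict"),
      reasons = attr(hp, "discard_reasons"))
    rm(hp); gc()
    del <- cfg$genome$deletions[1]
    eq <- equalize_snv_density(v, cfg$genome,
                               list(del$chrom, del$start, del$end), seed = 3)
    # only haplotype-informative pairs feed the homolog matrices
    list(config = cfg, pairs = informative, variants = v, equalization = eq,
         stats = stats)
  })
}

# per-homolog 40-kbp matrices of the capture patient
capture_hapset_40k <- function() {
  cached("capture_hapset_40k", function() {
    cap <- capture_patient()
    bins <- make_bins(cap$config$genome, cap$config$sim_resolution)
    build_haplotype_matrix(cap$pairs, bins)
  })
}

# compartment-label accuracy of PC1 on checkerboard simulations, 5 seeds
checkerboard_pc1_accuracies <- function() {
  cached("pc1_acc", function() {
    vapply(1:5, function(sd) {
      cfg <- cohort_config(seed = sd, genome = genome_model(c(chrA = 50e6)),
                           tad_strength = 1, hotspots = data.frame())
      set.seed(sd)
      cm <- simulate_bin_matrix(cfg, "ctrl", "H1")
      bins5 <- make_bins(cfg$genome, 5e5)
      e <- data.table::copy(cm$entries)
      f <- 5e5 / cfg$sim_resolution
      e[, `:=`(bin1 = bin1 %/% f, bin2 = bin2 %/% f)]
      cm5 <- contact_matrix(e, bins5, "raw")
      oe <- observed_over_expected(cm5, "chrA")
      mids <- bins5$bins$start + 2.5e5
      truth <- true_compartment(cfg, "chrA", mids)
      cp <- compartment_pc1(oe, as.numeric(truth == "A"))
      mean(cp$label == truth, na.rm = TRUE)
    }, 0)
  })
}

# fraction of true domain boundaries recovered within one 40-kbp bin
tad_recovery_fraction <- function() {
  cached("tad_recovery", function() {
    cfg <- cohort_config(seed = 23, genome = genome_model(c(chrA = 20e6)),
                         compartment_strength = 1, hotspots = data.frame())
    set.seed(23)
    cm <- simulate_bin_matrix(cfg, "ctrl", "H1")
    di <- directionality_index(cm, "chrA")
    doms <- call_domains(di, cm$bins)
    truth <- true_tad_boundaries(cfg, "chrA")
    called <- sort(unique(c(doms$start, doms$end)))
    mean(vapply(truth, function(b)
      any(abs(called - b) <= cfg$sim_resolution), TRUE))
  })
}

# Pearson correlation of the two homologs' DI away from the deletion
di_homolog_correlation <- function() {
  cached("di_homolog_cor", function() {
    cap <- capture_patient()
    cset <- capture_hapset_40k()
    di1 <- directionality_index(cset$mean$H1, "chr22s")
    di2 <- directionality_index(cset$mean$H2, "chr22s")
    bins <- make_bins(cap$config$genome, cap$config$sim_resolution)
    away <- bins$bins$start + cap$config$sim_resolution < 18.5e6 - 2e6 |
      bins$bins$start > 21.5e6 + 2e6
    stats::cor(di1$di[away], di2$di[away])
  })
}

# haplotype-resolved pairs of the first deletion sample of the default cohort
default_hap_pairs <- function() {
  cached("default_hap_pairs", function() {
    co <- default_cohort()
    cfg <- co$config
    sid <- names(co$statuses)[co$statuses == "del"][1]
    smp <- co$samples[[sid]]
    flt <- filter_pairs(smp$pairs, cfg$genome, cfg$library_fragment_length,
                        "haplotype")
    assign_pairs_haplotype(flt, smp$tags, smp$variants)
  })
}
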