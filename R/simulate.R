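#' Synthetic study configuration
#'
#' Defines a fully self-contained synthetic study: a small genome, a panel of
#' binned count tracks with negative-binomial noise, a set of risk variants
#' and a benign candidate pool placed with the same nearest-TSS distance
#' distribution, and a planted subset of informative features whose bin means
#' are shifted (up for enriched, down for depleted) at risk-variant bins.
#' Defaults emulate a single well-powered disease: 100 risk variants, a
#' 10,000-variant benign pool, 1000 features of which 50 are informative at a
#' 3-fold mean shift over a NB(mean 5, size 2) background on a 2 x 1 Mb
#' genome in 200-bp bins.
#'
#' @param chrom_lengths named chromosome lengths (bp).
#' @param bin_width bin width (bp).
#' @param n_features number of epigenomic tracks.
#' @param n_informative number of planted informative tracks.
#' @param enriched_frac fraction of informative tracks enriched (the rest
#'   depleted) at risk variants.
#' @param fold mean fold-change at risk-variant bins (`fold = 1` plants no
#'   signal: the null configuration).
#' @param mu0 background negative-binomial mean per bin.
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param n_risk number of risk variants.
#' @param pool_size benign candidate pool size.
#' @param n_tss transcription start sites scattered over the genome.
#' @param max_tss_distance maximum simulated variant-to-TSS distance (bp).
#' @param peak_quantile count quantile used when deriving peak tracks.
#' @param disease disease tag for the simulated variants.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(chrom_lengths = c(chrS1 = 1e6, chrS2 = 1e6),
                              bin_width = 200L, n_features = 1000L,
                              n_informative = 50L, enriched_frac = 0.5,
                              fold = 3, mu0 = 5, dispersion = 2,
                              n_risk = 100L, pool_size = 10000L,
                              n_tss = 60L, max_tss_distance = 2e5,
                              peak_quantile = 0.90,
                              disease = "synthetic_disease") {
  chrom_lengths <- unlist(chrom_lengths)  # accept YAML-style named lists
  stopifnot(n_informative <= n_features, fold > 0, mu0 > 0, dispersion > 0,
            n_risk >= 1, pool_size >= n_risk, n_tss >= length(chrom_lengths))
  structure(as.list(environment()), class = "simulation_config")
}

.histone_marks <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K9me1", "H3K9me3",
                    "H3K27me3", "H3K27ac", "H3K36me3", "H3K9ac", "H3K4ac",
                    "H3K79me2", "H4K20me1", "H2A.Z", "H3K23ac", "H3K14ac")
.tf_names <- c("CTCF", "JunD", "p300", "GABPA", "SP1", "YY1", "MAX", "EGR1",
               "ELF1", "USF1", "REST", "RAD21", "SRF", "TCF12", "ZBTB33")

# place points near randomly chosen TSSs with log-uniform distances;
# the same generator is used for risk variants and the benign pool, so the
# nearest-TSS distance distributions agree by construction
place_near_tss <- function(n, tss, chrom_lengths, max_d) {
  pick <- sample(nrow(tss), n, replace = TRUE)
  d <- round(10^stats::runif(n, 0, log10(max_d)))
  side <- sample(c(-1L, 1L), n, replace = TRUE)
  pos <- tss$pos[pick] + side * d
  len <- chrom_lengths[tss$chrom[pick]]
  pos <- pmin(pmax(pos, 1L), len)
  data.frame(chrom = tss$chrom[pick], pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Generates tracks, a manifest, TSS annotation, risk variants, a benign
#' pool and the planted ground truth, deterministically from the seed.
#' Background bins draw from NB(`mu0`, `dispersion`); for informative
#' enriched features the bins containing risk variants draw from mean
#' `mu0 * fold`, for depleted ones from `mu0 / fold`. Non-informative
#' features are identically distributed at risk and benign positions.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed; the same seed reproduces the dataset bit for
#'   bit.
#' @return an object of class `epirisk_sim`: list with `tracks` (read
#'   representation), `manifest`, `tss`, `risk`, `pool`, `truth`
#'   (`data.frame` of informative `track_id` and planted `direction`, plus
#'   risk ids as attribute), `genome` and `cfg`.
#' @export
simulate_dataset <- function(cfg = simulation_config(), seed = 1L) {
  stopifnot(inherits(cfg, "simulation_config"))
  genome <- binned_genome(cfg$chrom_lengths, cfg$bin_width)
  with_seed(derive_seed(seed, "simulate_dataset"), {
    # TSS: at least one per chromosome, the rest uniform
    chroms <- names(cfg$chrom_lengths)
    tss_chrom <- c(chroms, sample(chroms, cfg$n_tss - length(chroms), replace = TRUE))
    tss <- data.frame(chrom = tss_chrom,
                      pos = vapply(tss_chrom, function(ch)
                        sample.int(cfg$chrom_lengths[[ch]], 1L), integer(1)),
                      stringsAsFactors = FALSE)
    rownames(tss) <- NULL
    risk_pos <- place_near_tss(cfg$n_risk, tss, cfg$chrom_lengths, cfg$max_tss_distance)
    pool_pos <- place_near_tss(cfg$pool_size, tss, cfg$chrom_lengths, cfg$max_tss_distance)
    risk <- variant_table(risk_pos$chrom, risk_pos$pos,
                          sprintf("risk%05d", seq_len(cfg$n_risk)),
                          "risk", cfg$disease)
    pool <- variant_table(pool_pos$chrom, pool_pos$pos,
                          sprintf("pool%06d", seq_len(cfg$pool_size)),
                          "benign", cfg$disease)
    # planted informative features and their directions
    info_idx <- sort(sample.int(cfg$n_features, cfg$n_informative))
    n_enr <- round(cfg$enriched_frac * cfg$n_informative)
    dir <- rep("depleted", cfg$n_informative)
    if (n_enr > 0) dir[seq_len(n_enr)] <- "enriched"
    dir <- sample(dir)
    # feature metadata: categories in field-realistic proportions
    cat_pool <- c(rep("histone", 55), rep("tf", 32), rep("open_chromatin", 10),
                  rep("rna_pol", 3))
    category <- sample(cat_pool, cfg$n_features, replace = TRUE)
    fac <- character(cfg$n_features)
    fac[category == "histone"] <- rep_len(.histone_marks, sum(category == "histone"))
    fac[category == "tf"] <- rep_len(.tf_names, sum(category == "tf"))
    fac[category == "open_chromatin"] <- rep_len(c("DNase", "FAIRE"),
                                                 sum(category == "open_chromatin"))
    fac[category == "rna_pol"] <- rep_len(c("Pol2", "Pol3"), sum(category == "rna_pol"))
    cell <- sprintf("cell%02d", rep_len(1:20, cfg$n_features))
    src <- rep_len(c("REMC", "ENCODE"), cfg$n_features)
    risk_bins <- split(bin_index(risk$pos, cfg$bin_width) + 1L, risk$chrom)
    tracks <- vector("list", cfg$n_features)
    truth_dir <- rep(NA_character_, cfg$n_features)
    truth_dir[info_idx] <- dir
    for (j in seq_len(cfg$n_features)) {
      payload <- lapply(chroms, function(ch)
        as.numeric(stats::rnbinom(n_bins(genome, ch), mu = cfg$mu0,
                                  size = cfg$dispersion)))
      names(payload) <- chroms
      if (!is.na(truth_dir[j]) && cfg$fold != 1) {
        mu <- if (truth_dir[j] == "enriched") cfg$mu0 * cfg$fold else cfg$mu0 / cfg$fold
        for (ch in names(risk_bins)) {
          b <- unique(risk_bins[[ch]])
          payload[[ch]][b] <- as.numeric(stats::rnbinom(length(b), mu = mu,
                                                        size = cfg$dispersion))
        }
      }
      tracks[[j]] <- feature_track(sprintf("trk%04d", j), fac[j], cell[j],
                                   src[j], category[j], "read", payload,
                                   total_reads = sum(vapply(payload, sum, numeric(1))))
    }
  })
  manifest <- data.frame(
    track_id = vapply(tracks, `[[`, character(1), "track_id"),
    factor = fac, cell_line = cell, source = src, category = category,
    representation = "read",
    path = NA_character_,
    total_reads = vapply(tracks, `[[`, numeric(1), "total_reads"),
    stringsAsFactors = FALSE)
  truth <- data.frame(track_id = manifest$track_id[info_idx],
                      direction = truth_dir[info_idx], stringsAsFactors = FALSE)
  attr(truth, "risk_ids") <- risk$id
  structure(list(tracks = tracks, manifest = manifest, tss = tss, risk = risk,
                 pool = pool, truth = truth, genome = genome, cfg = cfg),
            class = "epirisk_sim")
}

#' @export
print.epirisk_sim <- function(x, ...) {
  cat(sprintf("<epirisk_sim> %d tracks (%d informative), %d risk variants, pool %d, %d TSS\n",
              length(x$tracks), nrow(x$truth), nrow(x$risk), nrow(x$pool), nrow(x$tss)))
  invisible(x)
}

#' Derive a peak track from a read track
#'
#' Peaks are the maximal runs of bins whose count reaches the given quantile
#' of the track's own bin counts, mirroring how called peaks coarsen a count
#' signal into a binary annotation.
#'
#' @param track a read-representation `feature_track`.
#' @param genome the `binned_genome` the track lives on.
#' @param quantile count quantile defining the peak threshold (default 0.90).
#' @return a peak-representation `feature_track` (same metadata).
#' @export
track_to_peaks <- function(track, genome, quantile = 0.90) {
  stopifnot(track$representation == "read")
  thr <- stats::quantile(unlist(track$payload, use.names = FALSE), quantile,
                         names = FALSE)
  w <- genome$bin_width
  hot_by_chrom <- lapply(track$payload, function(cnt) which(cnt >= thr))
  chrom <- rep(names(hot_by_chrom), lengths(hot_by_chrom))
  hot <- unlist(hot_by_chrom, use.names = FALSE)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = (hot - 1L) * w + 1L, end = hot * w)))
  feature_track(track$track_id, track$factor, track$cell_line, track$source,
                track$category, "peak", gr)
}

#' Direct matrix-level synthetic generator
#'
#' A fast path producing the annotation matrix the track-level generator
#' would yield, without materializing tracks: each feature column draws
#' NB(`mu0`, `dispersion`) counts, and informative columns shift the risk
#' rows' mean by `fold` (up or down). Used for evaluation-protocol studies
#' where only the matrix matters.
#'
#' @inheritParams simulation_config
#' @param n_benign number of benign rows.
#' @param seed integer seed.
#' @return list with `x` (an `annotation_matrix`), `labels`, and `truth`
#'   (`track_id`, `direction`).
#' @export
simulate_annotation <- function(n_risk = 100L, n_benign = 1000L,
                                n_features = 1000L, n_informative = 50L,
                                enriched_frac = 0.5, fold = 3, mu0 = 5,
                                dispersion = 2, seed = 1L) {
  stopifnot(n_informative <= n_features)
  n <- n_risk + n_benign
  labels <- c(rep("risk", n_risk), rep("benign", n_benign))
  with_seed(derive_seed(seed, "simulate_annotation"), {
    x <- matrix(as.numeric(stats::rnbinom(n * n_features, mu = mu0,
                                          size = dispersion)),
                nrow = n, ncol = n_features)
    info <- sort(sample.int(n_features, n_informative))
    n_enr <- round(enriched_frac * n_informative)
    dir <- sample(rep(c("enriched", "depleted"),
                      c(n_enr, n_informative - n_enr)))
    for (i in seq_along(info)) {
      mu <- if (dir[i] == "enriched") mu0 * fold else mu0 / fold
      x[seq_len(n_risk), info[i]] <- as.numeric(stats::rnbinom(n_risk, mu = mu,
                                                               size = dispersion))
    }
  })
  ids <- sprintf("trk%04d", seq_len(n_features))
  colnames(x) <- ids
  rownames(x) <- c(sprintf("risk%05d", seq_len(n_risk)),
                   sprintf("ctrl%05d", seq_len(n_benign)))
  meta <- data.frame(track_id = ids, factor = rep_len(.histone_marks, n_features),
                     cell_line = "cell01", source = "REMC",
                     category = "histone", representation = "read",
                     stringsAsFactors = FALSE)
  list(x = annotation_matrix(x, meta), labels = labels,
       truth = data.frame(track_id = ids[info], direction = dir,
                          stringsAsFactors = FALSE))
}

#' Feature manifest fixture mirroring the published feature panel
#'
#' A synthetic manifest whose per-source feature counts reproduce the
#' published summary of the full panel: REMC DNase 73, REMC histone 735,
#' ENCODE DNase 80, ENCODE FAIRE 31, HAIB TF 292, SYDH TF 279, ENCODE
#' histone 267 and ENCODE RNA polymerase 49 features (1806 in total:
#' 1002 histone, 571 TF, 184 open chromatin, 49 RNA polymerase). Factor and
#' cell-line labels are synthetic placeholders cycled through realistic
#' name pools; only the counts and category structure are meaningful.
#'
#' @return a manifest `data.frame` with 1806 rows.
#' @export
table1_manifest_fixture <- function() {
  mk <- function(n, source, category, factors, cells, prefix) {
    data.frame(track_id = sprintf("%s%04d", prefix, seq_len(n)),
               factor = rep_len(factors, n),
               cell_line = sprintf("C%03d", rep_len(seq_len(cells), n)),
               source = source, category = category, representation = "read",
               path = NA_character_, total_reads = NA_real_,
               stringsAsFactors = FALSE)
  }
  more_marks <- c(.histone_marks, paste0("H2BK", c(5, 12, 15, 20, 120), "ac"),
                  paste0("H2AK", c(5, 9), "ac"), paste0("H4K", c(5, 8, 12, 91), "ac"),
                  "H3K56ac", "H3K18ac", "H3T11ph", "H3K9me2", "H3K27me1",
                  paste0("H3K", c(4, 9, 14, 18, 23, 36, 56), "me0"),
                  paste0("H4K", c(16, 20), "ac"), "H2A.Zac", "H3ac")
  more_tfs <- c(.tf_names, sprintf("TF%03d", seq_len(85)))
  rbind(
    mk(73,  "REMC",        "open_chromatin", "DNase", 73, "remc_dnase"),
    mk(735, "REMC",        "histone", more_marks[1:31], 109, "remc_hist"),
    mk(80,  "ENCODE",      "open_chromatin", "DNase", 80, "enc_dnase"),
    mk(31,  "ENCODE",      "open_chromatin", "FAIRE", 31, "enc_faire"),
    mk(292, "ENCODE-HAIB", "tf", more_tfs[1:76], 19, "haib_tf"),
    mk(279, "ENCODE-SYDH", "tf", more_tfs[1:100], 31, "sydh_tf"),
    mk(267, "ENCODE",      "histone", more_marks[1:42], 18, "enc_hist"),
    mk(49,  "ENCODE",      "rna_pol", c("Pol2", "Pol3", "Pol2-4H8"), 31, "enc_pol"))
}

#' Write a simulated dataset to disk
#'
#' Emits bedGraph tracks, the manifest TSV (with relative paths filled in),
#' variant and TSS TSVs and the ground-truth TSV, all plain text.
#'
#' @param sim an `epirisk_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  man <- sim$manifest
  for (i in seq_along(sim$tracks)) {
    rel <- file.path("tracks", paste0(man$track_id[i], ".bedgraph"))
    write_bedgraph_track(sim$tracks[[i]], file.path(dir, rel), sim$genome)
    man$path[i] <- rel
  }
  write_manifest(man, file.path(dir, "manifest.tsv"))
  write_variants(sim$risk, file.path(dir, "risk.tsv"))
  write_variants(sim$pool, file.path(dir, "benign_pool.tsv"))
  utils::write.table(sim$tss, file.path(dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(chrom = names(sim$genome$chrom_lengths),
                                length = as.integer(sim$genome$chrom_lengths)),
                     file.path(dir, "genome.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
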