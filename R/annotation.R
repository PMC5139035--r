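#' Binned genome segmentation
#'
#' The genome is cut into fixed-width bins (200 bp by default) and every
#' read-representation feature stores one value per bin; a variant's feature
#' value is read off the bin containing it.
#'
#' @param chrom_lengths named integer vector, chromosome -> length in bp.
#' @param bin_width bin width in bp (default 200).
#' @return an object of class `binned_genome`.
#' @export
binned_genome <- function(chrom_lengths, bin_width = 200L) {
  stopifnot(bin_width > 0, length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  structure(list(bin_width = as.integer(bin_width),
                 chrom_lengths = vapply(chrom_lengths, as.integer, integer(1))),
            class = "binned_genome")
}

n_bins <- function(genome, chrom) {
  as.integer(ceiling(genome$chrom_lengths[[chrom]] / genome$bin_width))
}

#' Bin ordinal of a 1-based position
#'
#' @param pos 1-based position(s).
#' @param width bin width in bp (default 200).
#' @return 0-based bin ordinal(s): `floor((pos - 1) / width)`.
#' @export
bin_index <- function(pos, width = 200L) {
  if (any(pos < 1L)) stopf("positions must be >= 1 (1-based)")
  as.integer(floor((as.numeric(pos) - 1) / width))
}

.track_sources <- c("REMC", "ENCODE-HAIB", "ENCODE-SYDH", "ENCODE")
.track_categories <- c("histone", "tf", "open_chromatin", "rna_pol", "genomic")

#' Construct an epigenomic feature track
#'
#' A track is one (factor, cell line, source) signal in one of three
#' representations: `read` (per-bin counts, dense per chromosome), `peak`
#' (an interval set, stored as a sorted non-overlapping `GRanges`), or
#' `score` (a per-base score such as conservation, stored as `GRanges` with a
#' `score` column; positions not covered score 0).
#'
#' @param track_id unique track identifier.
#' @param factor assayed factor (e.g. `H3K9me3`, `CTCF`, `DNase`).
#' @param cell_line cell line or tissue.
#' @param source data source, one of `r paste(.track_sources, collapse = ", ")`.
#' @param category one of `r paste(.track_categories, collapse = ", ")`.
#' @param representation `"read"`, `"peak"` or `"score"`.
#' @param payload named list of per-chromosome numeric count vectors (`read`)
#'   or a `GRanges` (`peak`/`score`).
#' @param total_reads library size; required (positive) for `read` tracks.
#' @return an object of class `feature_track`.
#' @export
feature_track <- function(track_id, factor, cell_line, source, category,
                          representation = c("read", "peak", "score"),
                          payload, total_reads = NA_real_) {
  representation <- match.arg(representation)
  source <- match.arg(source, .track_sources)
  category <- match.arg(category, .track_categories)
  if (representation == "read") {
    stopifnot(is.list(payload), !is.null(names(payload)))
    if (!is.finite(total_reads) || total_reads <= 0)
      stopf("read track '%s' requires positive total_reads", track_id)
    if (any(unlist(lapply(payload, function(x) any(x < 0)))))
      stopf("read track '%s' has negative bin counts", track_id)
  } else {
    stopifnot(methods::is(payload, "GRanges"))
    if (representation == "peak")
      payload <- GenomicRanges::reduce(GenomicRanges::sort(payload))
  }
  structure(list(track_id = as.character(track_id), factor = as.character(factor),
                 cell_line = as.character(cell_line), source = source,
                 category = category, representation = representation,
                 payload = payload, total_reads = as.numeric(total_reads)),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track> %s: %s in %s [%s, %s, %s]\n", x$track_id,
              x$factor, x$cell_line, x$source, x$category, x$representation))
  invisible(x)
}

#' Merge read-representation replicates
#'
#' Biological replicates of the same factor in the same cell line are merged
#' by summing per-bin counts; library sizes add.
#'
#' @param tracks list of `feature_track`s sharing factor, cell line and
#'   `read` representation.
#' @return one merged `feature_track`.
#' @export
merge_read_replicates <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  t0 <- tracks[[1L]]
  for (t in tracks) {
    if (t$representation != "read") stopf("merge_read_replicates: track '%s' is not read-representation", t$track_id)
    if (t$factor != t0$factor || t$cell_line != t0$cell_line)
      stopf("replicate mismatch: '%s' (%s/%s) vs '%s' (%s/%s)",
            t$track_id, t$factor, t$cell_line, t0$track_id, t0$factor, t0$cell_line)
  }
  if (length(tracks) == 1L) return(t0)
  payload <- t0$payload
  for (t in tracks[-1L]) for (ch in names(t$payload)) {
    payload[[ch]] <- if (is.null(payload[[ch]])) t$payload[[ch]] else payload[[ch]] + t$payload[[ch]]
  }
  feature_track(t0$track_id, t0$factor, t0$cell_line, t0$source, t0$category,
                "read", payload, sum(vapply(tracks, `[[`, numeric(1), "total_reads")))
}

#' Merge peak-representation replicates
#'
#' Overlapping peaks across replicates are merged by taking the interval
#' union; the result is sorted and non-overlapping.
#'
#' @param tracks list of `feature_track`s sharing factor, cell line and
#'   `peak` representation.
#' @return one merged `feature_track`.
#' @export
merge_peak_replicates <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  t0 <- tracks[[1L]]
  for (t in tracks) {
    if (t$representation != "peak") stopf("merge_peak_replicates: track '%s' is not peak-representation", t$track_id)
    if (t$factor != t0$factor || t$cell_line != t0$cell_line)
      stopf("replicate mismatch: '%s' vs '%s'", t$track_id, t0$track_id)
  }
  parts <- lapply(tracks, `[[`, "payload")
  u <- GenomicRanges::reduce(GenomicRanges::GRanges(
    unlist(lapply(parts, function(g) as.character(GenomicRanges::seqnames(g)))),
    IRanges::IRanges(
      start = unlist(lapply(parts, GenomicRanges::start)),
      end = unlist(lapply(parts, GenomicRanges::end)))))
  feature_track(t0$track_id, t0$factor, t0$cell_line, t0$source, t0$category,
                "peak", u)
}

#' Subtract depth-adjusted input from ChIP counts
#'
#' ChIP-seq bins are normalized against the matched input library by
#' subtracting the input counts after scaling the input to the ChIP
#' sequencing depth: `max(0, chip - input * chip_total / input_total)` per
#' bin. Open-chromatin tracks (DNase-seq, FAIRE-seq) have no matched input and
#' bypass this step. Negative differences are floored at 0 by default.
#'
#' @param chip,control read-representation `feature_track`s on the same
#'   binning; `control` is the input library.
#' @param floor_negative floor negative normalized counts at 0 (default TRUE).
#' @return the normalized ChIP `feature_track` (library size unchanged).
#' @export
normalize_chip_vs_input <- function(chip, control, floor_negative = TRUE) {
  stopifnot(chip$representation == "read", control$representation == "read")
  if (!is.finite(control$total_reads) || control$total_reads <= 0)
    stopf("control track '%s' has zero or missing sequencing depth", control$track_id)
  scale <- chip$total_reads / control$total_reads
  payload <- chip$payload
  for (ch in names(payload)) {
    ctl <- control$payload[[ch]]
    if (is.null(ctl)) next
    z <- payload[[ch]] - ctl * scale
    if (floor_negative) z <- pmax(z, 0)
    payload[[ch]] <- z
  }
  out <- chip
  out$payload <- payload
  out
}

variant_granges <- function(v) {
  GenomicRanges::GRanges(v$chrom, IRanges::IRanges(start = v$pos, width = 1L))
}

#' Build the variants-by-features annotation matrix
#'
#' Each variant is annotated by every track: read columns hold the
#' (normalized) count of the variant's containing bin; peak columns hold 1
#' iff the variant base intersects a peak interval; score columns hold the
#' per-base score at the variant position (0 where uncovered).
#'
#' @param variants a variant table.
#' @param tracks list of merged/normalized `feature_track`s.
#' @param genome a `binned_genome`.
#' @return an object of class `annotation_matrix`: a list with `values`
#'   (numeric matrix, rows = variant ids, columns = track ids) and `col_meta`
#'   (per-column factor, cell line, source, category, representation).
#' @export
build_annotation_matrix <- function(variants, tracks, genome) {
  variants <- validate_variants(variants)
  stopifnot(inherits(genome, "binned_genome"))
  bad_chrom <- setdiff(unique(variants$chrom), names(genome$chrom_lengths))
  if (length(bad_chrom)) stopf("variant chromosome(s) not in genome: %s", paste(bad_chrom, collapse = ", "))
  over <- variants$pos > genome$chrom_lengths[variants$chrom]
  if (any(over)) stopf("variant(s) beyond chromosome length: %s",
                       paste(variants$id[over], collapse = ", "))
  ids <- vapply(tracks, `[[`, character(1), "track_id")
  if (anyDuplicated(ids)) stopf("duplicate track_id among tracks: '%s'", ids[duplicated(ids)][1L])
  bins <- bin_index(variants$pos, genome$bin_width)
  vgr <- variant_granges(variants)
  values <- matrix(0, nrow = nrow(variants), ncol = length(tracks),
                   dimnames = list(variants$id, ids))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    if (tr$representation == "read") {
      vj <- numeric(nrow(variants))
      for (ch in unique(variants$chrom)) {
        cnt <- tr$payload[[ch]]
        if (is.null(cnt)) stopf("track '%s' lacks chromosome '%s'", tr$track_id, ch)
        i <- which(variants$chrom == ch)
        vj[i] <- cnt[bins[i] + 1L]
      }
      values[, j] <- vj
    } else if (tr$representation == "peak") {
      values[, j] <- as.integer(IRanges::overlapsAny(vgr, tr$payload))
    } else {
      hit <- GenomicRanges::findOverlaps(vgr, tr$payload, select = "first")
      sc <- ifelse(is.na(hit), 0, tr$payload$score[hit])
      values[, j] <- sc
    }
  }
  col_meta <- data.frame(
    track_id = ids,
    factor = vapply(tracks, `[[`, character(1), "factor"),
    cell_line = vapply(tracks, `[[`, character(1), "cell_line"),
    source = vapply(tracks, `[[`, character(1), "source"),
    category = vapply(tracks, `[[`, character(1), "category"),
    representation = vapply(tracks, `[[`, character(1), "representation"),
    stringsAsFactors = FALSE)
  annotation_matrix(values, col_meta)
}

#' @rdname build_annotation_matrix
#' @param values numeric matrix (variant ids x track ids).
#' @param col_meta per-column metadata `data.frame`.
#' @export
annotation_matrix <- function(values, col_meta) {
  stopifnot(is.matrix(values), nrow(col_meta) == ncol(values),
            all(col_meta$track_id == colnames(values)))
  if (anyNA(values)) stopf("annotation matrix contains missing values")
  bin_cols <- col_meta$representation == "peak"
  if (any(bin_cols) && !all(values[, bin_cols, drop = FALSE] %in% c(0, 1)))
    stopf("peak columns must be binary 0/1")
  structure(list(values = values, col_meta = col_meta), class = "annotation_matrix")
}

#' @export
dim.annotation_matrix <- function(x) dim(x$values)

#' @export
as.matrix.annotation_matrix <- function(x, ...) x$values

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("<annotation_matrix> %d variants x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$col_meta$representation)),
                            table(x$col_meta$representation)), collapse = ", ")))
  invisible(x)
}

#' Subset an annotation matrix
#'
#' @param x an `annotation_matrix`.
#' @param i,j row (variant) and column (track) indices.
#' @param ... ignored.
#' @export
`[.annotation_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  annotation_matrix(x$values[i, j, drop = FALSE], x$col_meta[j, , drop = FALSE])
}
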