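#' Read a per-bin count track from bedGraph
#'
#' bedGraph intervals are 0-based half-open and must align to the bin grid of
#' `genome` (both boundaries multiples of the bin width); a misaligned
#' interval is an error naming the first offender. Intervals spanning several
#' bins assign their value to each covered bin; absent bins count 0.
#'
#' @param path bedGraph file.
#' @param genome a `binned_genome`.
#' @param track_id,factor,cell_line,source,category track metadata (see
#'   [feature_track()]).
#' @param total_reads library size; defaults to the sum of all bin counts.
#' @return a read-representation `feature_track`.
#' @export
read_bedgraph_track <- function(path, genome, track_id, factor, cell_line,
                                source = "ENCODE", category = "histone",
                                total_reads = NA_real_) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  w <- genome$bin_width
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  bad <- which(start0 %% w != 0L | end0 %% w != 0L)
  if (length(bad)) {
    b <- bad[1L]
    stopf("bedGraph interval not aligned to %d-bp bin grid: %s:%d-%d in '%s'",
          w, as.character(GenomicRanges::seqnames(gr))[b], start0[b], end0[b], path)
  }
  payload <- lapply(names(genome$chrom_lengths), function(ch) numeric(n_bins(genome, ch)))
  names(payload) <- names(genome$chrom_lengths)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chroms), names(payload))
  if (length(unknown)) stopf("bedGraph chromosome(s) not in genome: %s", paste(unknown, collapse = ", "))
  vals <- as.numeric(gr$score)
  for (i in seq_along(gr)) {
    b0 <- start0[i] %/% w; b1 <- end0[i] %/% w  # covered bins [b0, b1)
    payload[[chroms[i]]][(b0 + 1L):b1] <- vals[i]
  }
  if (!is.finite(total_reads)) total_reads <- sum(vapply(payload, sum, numeric(1)))
  feature_track(track_id, factor, cell_line, source, category, "read",
                payload, total_reads)
}

#' Write a read track as bedGraph
#'
#' Only non-zero bins are written (0-based half-open intervals, one bin per
#' line).
#'
#' @param track a read-representation `feature_track`.
#' @param path output file.
#' @param genome a `binned_genome`.
#' @export
write_bedgraph_track <- function(track, path, genome) {
  stopifnot(track$representation == "read")
  w <- genome$bin_width
  con <- file(path, "w"); on.exit(close(con))
  for (ch in names(track$payload)) {
    cnt <- track$payload[[ch]]
    nz <- which(cnt != 0)
    if (!length(nz)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", ch, (nz - 1L) * w,
                       pmin(nz * w, genome$chrom_lengths[[ch]] %/% w * w + w), cnt[nz]), con)
  }
  invisible(path)
}

#' Read a peak track from BED
#'
#' @param path BED3(+) file (0-based half-open; converted internally to the
#'   Bioconductor 1-based closed convention).
#' @inheritParams read_bedgraph_track
#' @return a peak-representation `feature_track` (peaks merged and sorted).
#' @export
read_peak_track <- function(path, track_id, factor, cell_line,
                            source = "ENCODE", category = "histone") {
  gr <- rtracklayer::import(path, format = "BED")
  feature_track(track_id, factor, cell_line, source, category, "peak", gr)
}

#' @rdname read_peak_track
#' @param track a peak `feature_track` to write.
#' @export
write_peak_track <- function(track, path) {
  stopifnot(track$representation == "peak")
  rtracklayer::export(track$payload, path, format = "BED")
  invisible(path)
}

#' Read or write a feature manifest
#'
#' The manifest maps each track to its metadata and payload file: TSV with
#' header `track_id factor cell_line source category representation path
#' total_reads`.
#'
#' @param path manifest TSV.
#' @return a `data.frame` with one row per track.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  need <- c("track_id", "factor", "cell_line", "source", "category",
            "representation", "path", "total_reads")
  miss <- setdiff(need, names(m))
  if (length(miss)) stopf("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  m
}

#' @rdname read_manifest
#' @param manifest manifest `data.frame` to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load all tracks listed in a manifest
#'
#' @param manifest manifest `data.frame` (see [read_manifest()]).
#' @param genome a `binned_genome` (needed for read tracks).
#' @param base_dir directory against which relative `path`s are resolved.
#' @return a list of `feature_track`s in manifest order.
#' @export
load_tracks <- function(manifest, genome, base_dir = ".") {
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    p <- if (file.exists(m$path)) m$path else file.path(base_dir, m$path)
    if (m$representation == "read")
      read_bedgraph_track(p, genome, m$track_id, m$factor, m$cell_line,
                          m$source, m$category, as.numeric(m$total_reads))
    else if (m$representation == "peak")
      read_peak_track(p, m$track_id, m$factor, m$cell_line, m$source, m$category)
    else stopf("manifest row %d: cannot load representation '%s' from file", i, m$representation)
  })
}

#' Serialize an annotation matrix as TSV
#'
#' The matrix is written as TSV (first column `id`, then one column per
#' track) with a sidecar column-metadata TSV at `<path>.meta.tsv`.
#'
#' @param am an `annotation_matrix`.
#' @param path output TSV path.
#' @export
write_annotation_matrix <- function(am, path) {
  d <- data.frame(id = rownames(am$values), am$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(am$col_meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_matrix
#' @export
read_annotation_matrix <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta <- utils::read.table(paste0(path, ".meta.tsv"), header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  values <- as.matrix(d[, -1L, drop = FALSE])
  rownames(values) <- d$id
  annotation_matrix(values, meta)
}
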