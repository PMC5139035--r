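#' Construct a variant table
#'
#' Variants are genomic points (1-based positions) with a class label and an
#' optional disease tag. Risk variants are GWAS-reported trait-associated index
#' SNPs used as surrogates for functional variants; benign variants are
#' controls with no reported association.
#'
#' @param chrom character chromosome names.
#' @param pos 1-based integer positions.
#' @param id unique string identifiers.
#' @param label `"risk"` or `"benign"`.
#' @param disease optional disease tag (recycled).
#' @return a `data.frame` with columns `chrom`, `pos`, `id`, `label`,
#'   `disease`.
#' @export
variant_table <- function(chrom, pos, id, label = "benign", disease = NA_character_) {
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  id = as.character(id), label = as.character(label),
                  disease = as.character(disease), stringsAsFactors = FALSE)
  validate_variants(v)
}

#' @rdname variant_table
#' @param v a variant table to validate.
#' @export
validate_variants <- function(v) {
  need <- c("chrom", "pos", "id", "label", "disease")
  miss <- setdiff(need, names(v))
  if (length(miss)) stopf("variant table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(v$pos < 1L)) stopf("variant positions must be >= 1 (1-based)")
  if (anyDuplicated(v$id)) stopf("variant ids are not unique: e.g. '%s'", v$id[duplicated(v$id)][1L])
  bad <- setdiff(unique(v$label), c("risk", "benign"))
  if (length(bad)) stopf("unknown variant label(s): %s", paste(bad, collapse = ", "))
  rownames(v) <- NULL
  v[, need]
}

#' Read and write variant tables
#'
#' The native format is TSV with header `chrom pos id label disease`
#' (`pos` 1-based). BED3+name files are also accepted on input; the 0-based
#' half-open `start` is converted to `pos = start + 1` and the name column
#' becomes the id.
#'
#' @param path file path; `.bed` extension (or `format = "bed"`) selects BED.
#' @param format `"auto"`, `"tsv"` or `"bed"`.
#' @param label,disease labels assigned to BED input (BED carries neither).
#' @return a validated variant table.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "bed"),
                          label = "benign", disease = NA_character_) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- if (!is.null(gr$name)) as.character(gr$name) else paste0("v", seq_along(gr))
    return(variant_table(as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr), ids, label, disease))
  }
  v <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "integer", "character",
                                        "character", "character"))
  validate_variants(v)
}

#' @rdname read_variants
#' @param v variant table to write.
#' @export
write_variants <- function(v, path) {
  utils::write.table(validate_variants(v), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read transcription start sites
#'
#' Accepts BED (the interval start, converted to 1-based, is taken as the TSS)
#' or a two-column `chrom<TAB>pos` TSV (1-based, no header required; a header
#' line is detected and skipped).
#'
#' @param path file path.
#' @return a `data.frame` with columns `chrom`, `pos`.
#' @export
read_tss <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      pos = GenomicRanges::start(gr), stringsAsFactors = FALSE))
  }
  first <- readLines(path, n = 1L)
  skip <- if (grepl("chrom", first, ignore.case = TRUE)) 1L else 0L
  d <- utils::read.table(path, sep = "\t", skip = skip,
                         col.names = c("chrom", "pos"),
                         colClasses = c("character", "integer"))
  d
}

# minimum distance of each query point to any site in (s_chrom, s_pos);
# Inf when the query chromosome has no site
min_dist_to_set <- function(q_chrom, q_pos, s_chrom, s_pos) {
  out <- rep(Inf, length(q_pos))
  for (ch in unique(q_chrom)) {
    qi <- which(q_chrom == ch)
    sp <- sort(s_pos[s_chrom == ch])
    if (!length(sp)) next
    idx <- findInterval(q_pos[qi], sp)
    lo <- ifelse(idx >= 1L, q_pos[qi] - sp[pmax(idx, 1L)], Inf)
    hi <- ifelse(idx < length(sp), sp[pmin(idx + 1L, length(sp))] - q_pos[qi], Inf)
    out[qi] <- pmin(abs(lo), abs(hi))
  }
  out
}

#' Distance to the nearest transcription start site
#'
#' The matching covariate for control construction: benign variants are
#' sampled so that their nearest-TSS distances match the risk variants'.
#'
#' @param v a variant table.
#' @param tss a TSS table (`chrom`, `pos`, both 1-based).
#' @return non-negative integer distances in bp, one per variant.
#' @export
nearest_tss_distance <- function(v, tss) {
  v <- validate_variants(v)
  missing_chrom <- setdiff(unique(v$chrom), unique(tss$chrom))
  if (length(missing_chrom))
    stopf("no TSS on chromosome(s): %s", paste(missing_chrom, collapse = ", "))
  as.integer(min_dist_to_set(v$chrom, v$pos, tss$chrom, tss$pos))
}

# log10 distance strata used for TSS matching; left-closed bins
.tss_strata_edges <- c(0, 1e2, 1e3, 1e4, 1e5, 1e6, Inf)

tss_stratum <- function(d) findInterval(d, .tss_strata_edges, rightmost.closed = FALSE)

#' TSS-distance-matched benign control sampling
#'
#' Samples `ratio` times as many benign controls as there are risk variants,
#' without replacement, so that the empirical distribution of nearest-TSS
#' distance matches the risk set stratum by stratum. Distances are binned on a
#' log10 scale with edges 0, 1e2, 1e3, 1e4, 1e5, 1e6, Inf bp. If a stratum's
#' pool is exhausted, the shortfall is borrowed from the nearest adjacent
#' stratum with a warning.
#'
#' @param risk risk variant table.
#' @param pool candidate-benign variant table, id-disjoint from `risk` and
#'   pre-filtered (e.g. by allele frequency) upstream.
#' @param tss TSS table.
#' @param ratio benign-to-risk size ratio (default 10).
#' @param seed integer seed; sampling is reproducible bit for bit.
#' @return a variant table of exactly `ratio * nrow(risk)` benign variants.
#' @export
match_benign_tss <- function(risk, pool, tss, ratio = 10L, seed = 1L) {
  risk <- validate_variants(risk); pool <- validate_variants(pool)
  pool <- pool[!pool$id %in% risk$id, , drop = FALSE]
  d_risk <- nearest_tss_distance(risk, tss)
  d_pool <- nearest_tss_distance(pool, tss)
  s_risk <- tss_stratum(d_risk)
  s_pool <- tss_stratum(d_pool)
  n_strata <- length(.tss_strata_edges) - 1L
  need <- tabulate(s_risk, nbins = n_strata) * ratio
  avail <- split(seq_len(nrow(pool)), factor(s_pool, levels = seq_len(n_strata)))
  take <- integer(0)
  with_seed(seed, {
    for (s in seq_len(n_strata)) {
      if (need[s] == 0L) next
      cand <- avail[[s]]
      k <- min(length(cand), need[s])
      if (k > 0L) {
        pick <- if (length(cand) == 1L) cand else sample(cand, k)
        take <- c(take, pick)
        avail[[s]] <- setdiff(cand, pick)
      }
      short <- need[s] - k
      if (short > 0L) {
        warnf("TSS stratum %d exhausted (%d short); borrowing from adjacent strata", s, short)
        for (off in seq_len(n_strata)) {
          for (nb in c(s - off, s + off)) {
            if (short == 0L || nb < 1L || nb > n_strata) next
            cand <- avail[[nb]]
            k2 <- min(length(cand), short)
            if (k2 > 0L) {
              pick <- if (length(cand) == 1L) cand else sample(cand, k2)
              take <- c(take, pick)
              avail[[nb]] <- setdiff(cand, pick)
              short <- short - k2
            }
          }
          if (short == 0L) break
        }
        if (short > 0L)
          stopf("stratum %d: pool insufficient even after borrowing (%d missing)", s, short)
      }
    }
  })
  out <- pool[sort(take), , drop = FALSE]
  out$label <- "benign"
  rownames(out) <- NULL
  out
}

#' Region-matched benign control sampling
#'
#' Alternative, more stringent control criterion: every sampled benign variant
#' must lie within `window_bp` (inclusive) of at least one risk variant on the
#' same chromosome.
#'
#' @inheritParams match_benign_tss
#' @param window_bp matching window in bp (default 10 kb).
#' @return a variant table of exactly `ratio * nrow(risk)` benign variants.
#' @export
match_benign_region <- function(risk, pool, window_bp = 10000L, ratio = 10L, seed = 1L) {
  risk <- validate_variants(risk); pool <- validate_variants(pool)
  pool <- pool[!pool$id %in% risk$id, , drop = FALSE]
  d <- min_dist_to_set(pool$chrom, pool$pos, risk$chrom, risk$pos)
  eligible <- which(d <= window_bp)
  n_out <- ratio * nrow(risk)
  if (length(eligible) < n_out)
    stopf("only %d pool variants lie within %d bp of a risk variant; %d needed",
          length(eligible), window_bp, n_out)
  take <- with_seed(seed, sample(eligible, n_out))
  out <- pool[sort(take), , drop = FALSE]
  out$label <- "benign"
  rownames(out) <- NULL
  out
}

#' Thin a variant set by genomic proximity
#'
#' Greedy scan over variants sorted by (chrom, pos): a variant is kept iff its
#' distance to the last kept variant on the same chromosome is at least
#' `min_gap_bp`, so no two retained variants on one chromosome are closer than
#' the gap. Used before cross-validation so that neither training nor testing
#' folds contain variants at the same or nearby locations.
#'
#' @param v variant table.
#' @param min_gap_bp minimum retained gap in bp (default 10 kb).
#' @return the thinned variant table (original row order of the kept rows).
#' @export
thin_by_proximity <- function(v, min_gap_bp = 10000L) {
  v <- validate_variants(v)
  o <- order(v$chrom, v$pos)
  keep <- logical(nrow(v))
  last_chrom <- ""; last_pos <- -Inf
  for (i in o) {
    if (v$chrom[i] != last_chrom || v$pos[i] - last_pos >= min_gap_bp) {
      keep[i] <- TRUE
      last_chrom <- v$chrom[i]; last_pos <- v$pos[i]
    }
  }
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude test variants near (or identical to) training variants
#'
#' Removes from `test` every variant lying within `window_bp` of any `train`
#' variant on the same chromosome, as well as exact id matches, to keep an
#' independent test set free of leakage from nearby training variants.
#'
#' @param test,train variant tables.
#' @param window_bp exclusion window in bp (default 10 kb).
#' @return the filtered `test` table.
#' @export
exclude_within <- function(test, train, window_bp = 10000L) {
  test <- validate_variants(test); train <- validate_variants(train)
  d <- min_dist_to_set(test$chrom, test$pos, train$chrom, train$pos)
  out <- test[d > window_bp & !test$id %in% train$id, , drop = FALSE]
  rownames(out) <- NULL
  out
}
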