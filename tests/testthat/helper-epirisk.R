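# small in-code fixtures shared across the suite

toy_genome <- function(len = 10000L, width = 200L, chroms = c("chrA", "chrB")) {
  binned_genome(stats::setNames(rep(len, length(chroms)), chroms), width)
}

# a read track with given dense per-chrom counts
toy_read_track <- function(counts, id = "t1", factor = "H3K9me3",
                           cell = "cellX", total = NULL) {
  if (is.null(total)) total <- sum(vapply(counts, sum, numeric(1)))
  feature_track(id, factor, cell, "REMC", "histone", "read", counts, total)
}

# a peak track from 0-based half-open intervals
toy_peak_track <- function(chrom, start0, end0, id = "p1", factor = "CTCF",
                           cell = "cellX") {
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = start0 + 1L, end = end0))
  feature_track(id, factor, cell, "ENCODE", "tf", "peak", gr)
}

random_variants <- function(n, genome, prefix = "v", label = "benign",
                            seed = 1L) {
  set.seed(seed)
  chrom <- sample(names(genome$chrom_lengths), n, replace = TRUE)
  pos <- vapply(chrom, function(ch) sample.int(genome$chrom_lengths[[ch]], 1L),
                integer(1))
  variant_table(chrom, pos, sprintf("%s%04d", prefix, seq_len(n)), label)
}

# independent brute-force minimum pairwise distance (same chromosome)
brute_min_dist <- function(qc, qp, sc, sp) {
  vapply(seq_along(qp), function(i) {
    j <- which(sc == qc[i])
    if (!length(j)) return(Inf)
    min(abs(sp[j] - qp[i]))
  }, numeric(1))
}

# two-sided Fisher p by explicit hypergeometric enumeration
fisher_enum_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# AUC by explicit pair counting over all risk/benign pairs
auc_pairs <- function(scores, labels) {
  r <- scores[labels == "risk"]; b <- scores[labels == "benign"]
  tot <- 0
  for (x in r) tot <- tot + sum(x > b) + 0.5 * sum(x == b)
  tot / (length(r) * length(b))
}
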