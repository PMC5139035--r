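#' Binomial over-representation p-value for a factor
#'
#' Tests whether a factor (e.g. H3K9me3) is over-represented among the
#' informative features of one disease. With `n_i` informative features out
#' of `N` total and `k_ij` informative features of factor j, the default
#' (`"as_printed"`) tail is
#' `P(X > k_ij) = sum_{x = k_ij + 1}^{n_i} C(n_i, x) p^x (1 - p)^{n_i - x}`
#' with `p = n_i / N` — a binomial on `n_i` trials, which does not involve
#' the factor's feature count `m_ij`. The `"m_trials"` variant instead uses
#' `m_ij` trials at the same success probability (requires `m_ij`); both are
#' offered because the defined-but-unused `m_ij` suggests the printed trial
#' count may be unintended, and neither reading is guessed to be "the"
#' intended one.
#'
#' @param n_i number of informative features in the disease.
#' @param N total number of features.
#' @param k_ij informative features of the factor.
#' @param variant `"as_printed"` (default) or `"m_trials"`.
#' @param m_ij the factor's total feature count (only for `"m_trials"`).
#' @return the upper-tail p-value.
#' @export
factor_overrep_pvalue <- function(n_i, N, k_ij, variant = c("as_printed", "m_trials"),
                                  m_ij = NULL) {
  variant <- match.arg(variant)
  if (k_ij < 0 || n_i < 0 || n_i > N) stopf("require 0 <= n_i <= N and k_ij >= 0")
  if (k_ij > n_i) stopf("k_ij (%d) exceeds n_i (%d)", k_ij, n_i)
  p_hat <- n_i / N
  if (variant == "as_printed")
    return(stats::pbinom(k_ij, size = n_i, prob = p_hat, lower.tail = FALSE))
  if (is.null(m_ij)) stopf("variant 'm_trials' requires m_ij")
  if (k_ij > m_ij) stopf("k_ij (%d) exceeds m_ij (%d)", k_ij, m_ij)
  stats::pbinom(k_ij, size = m_ij, prob = p_hat, lower.tail = FALSE)
}

#' Tally over-represented factors across diseases
#'
#' Applies the Bonferroni-corrected threshold `alpha / D` to the
#' per-(disease, factor) p-values and counts, for each factor, the number of
#' diseases in which it is over-represented ("frequent fliers").
#'
#' @param per_disease `data.frame` with columns `disease`, `factor`,
#'   `p_value` (e.g. the `table` component of [factor_enrichment()]).
#' @param alpha family-wise error rate (default 0.05).
#' @param D number of diseases tested (defaults to the number of distinct
#'   diseases in `per_disease`).
#' @return a named integer vector, factor -> count of diseases, sorted
#'   decreasing; the threshold used is attached as attribute `"threshold"`.
#' @export
tally_overrepresentation <- function(per_disease, alpha = 0.05, D = NULL) {
  if (is.null(D)) D <- length(unique(per_disease$disease))
  if (D < 1L) stopf("D must be >= 1")
  thr <- alpha / D
  hit <- per_disease$p_value < thr
  tal <- vapply(split(hit, per_disease$factor), sum, integer(1))
  tal <- sort(tal, decreasing = TRUE)
  attr(tal, "threshold") <- thr
  tal
}

#' Factor over-representation analysis across diseases
#'
#' For each disease's feature-selection table, counts the informative
#' features per factor and computes the binomial over-representation p-value;
#' then tallies over-represented factors across diseases at the Bonferroni
#' threshold `alpha / D`.
#'
#' @param selections named list (disease -> feature-selection `data.frame`
#'   with `track_id` and logical `selected`; see [compute_feature_pvalues()]
#'   and [apply_threshold()]).
#' @param manifest `data.frame` mapping `track_id` to `factor` (e.g. a
#'   feature manifest); ignored if each selection table already carries a
#'   `factor` column.
#' @param alpha family-wise error rate (default 0.05).
#' @param variant p-value variant, see [factor_overrep_pvalue()].
#' @return an object of class `factor_enrichment`: list with `table`
#'   (per disease and factor: `n_i`, `N`, `m_ij`, `k_ij`, `p_hat`,
#'   `p_value`, `over_represented`), `tally`, `threshold` and `D`.
#' @export
factor_enrichment <- function(selections, manifest = NULL, alpha = 0.05,
                              variant = "as_printed") {
  stopifnot(is.list(selections), !is.null(names(selections)))
  D <- length(selections)
  rows <- list()
  for (d in names(selections)) {
    sel <- selections[[d]]
    if (is.null(sel$factor)) {
      if (is.null(manifest)) stopf("selection table for '%s' lacks a factor column and no manifest given", d)
      sel$factor <- manifest$factor[match(sel$track_id, manifest$track_id)]
    }
    if (anyNA(sel$factor)) stopf("unmapped track_id(s) in disease '%s'", d)
    N <- nrow(sel)
    n_i <- sum(sel$selected)
    for (fc in unique(sel$factor)) {
      in_f <- sel$factor == fc
      m_ij <- sum(in_f)
      k_ij <- sum(in_f & sel$selected)
      rows[[length(rows) + 1L]] <- data.frame(
        disease = d, factor = fc, n_i = n_i, N = N, m_ij = m_ij, k_ij = k_ij,
        p_hat = n_i / N,
        p_value = factor_overrep_pvalue(n_i, N, k_ij, variant, m_ij = m_ij),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  thr <- alpha / D
  tab$over_represented <- tab$p_value < thr
  tal <- tally_overrepresentation(tab, alpha = alpha, D = D)
  structure(list(table = tab, tally = tal, threshold = thr, D = D),
            class = "factor_enrichment")
}

#' @export
print.factor_enrichment <- function(x, ...) {
  cat(sprintf("Factor over-representation across %d disease(s), Bonferroni p < %g\n",
              x$D, x$threshold))
  top <- utils::head(x$tally[x$tally > 0], 10L)
  if (length(top)) {
    cat("Top factors (diseases over-represented in):\n")
    for (i in seq_along(top)) cat(sprintf("  %-12s %d\n", names(top)[i], top[i]))
  } else cat("  no factor over-represented\n")
  invisible(x)
}

#' @rdname factor_enrichment
#' @param x a `factor_enrichment` result.
#' @param path output prefix: writes `<path>.table.tsv` and
#'   `<path>.tally.tsv`.
#' @export
write_enrichment <- function(x, path) {
  utils::write.table(x$table, paste0(path, ".table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(factor = names(x$tally), n_diseases = as.integer(x$tally)),
                     paste0(path, ".tally.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
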