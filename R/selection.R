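#' Welch t-test p-value for one continuous feature
#'
#' Two-sided Welch (unequal-variance) t-test contrasting a count feature at
#' risk versus benign variants; the t statistic is positive when the risk mean
#' exceeds the benign mean. The Welch flavor is used because the benign set is
#' ten times larger and typically heteroskedastic. By convention two constant,
#' equal groups give `t = 0, p = 1`; constant groups with different values
#' give `p = 0`.
#'
#' @param x_risk,x_benign numeric vectors (each of length >= 2).
#' @return a list with `statistic` (t) and `p_value`.
#' @export
feature_pvalue_continuous <- function(x_risk, x_benign) {
  if (length(x_risk) < 2L || length(x_benign) < 2L)
    stopf("each group needs >= 2 observations (got %d and %d)", length(x_risk), length(x_benign))
  if (stats::var(x_risk) == 0 && stats::var(x_benign) == 0) {
    if (mean(x_risk) == mean(x_benign)) return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(mean(x_risk) - mean(x_benign)) * Inf, p_value = 0))
  }
  ht <- stats::t.test(x_risk, x_benign, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Fisher's exact test p-value for one binary feature
#'
#' Two-by-two contingency table of peak presence versus class; the two-sided
#' p-value sums the probabilities of all tables (at fixed margins) no more
#' probable than the observed one.
#'
#' @param k_risk_in,k_risk_out risk variants inside / outside peaks.
#' @param k_benign_in,k_benign_out benign variants inside / outside peaks.
#' @return the two-sided p-value.
#' @export
feature_pvalue_binary <- function(k_risk_in, k_risk_out, k_benign_in, k_benign_out) {
  counts <- c(k_risk_in, k_risk_out, k_benign_in, k_benign_out)
  if (any(counts < 0)) stopf("contingency counts must be non-negative")
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("contingency table has an empty margin")
  stats::fisher.test(tab)$p.value
}

# vectorized Welch t over matrix columns; returns t, df, p per column.
# cross-checked against stats::t.test in the test suite.
welch_t_cols <- function(x, risk, benign) {
  x1 <- x[risk, , drop = FALSE]; x2 <- x[benign, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)  # guard tiny negative rounding
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (m1 == m2)
    t[eq] <- 0; p[eq] <- 1
    ne <- degen & (m1 != m2)
    t[ne] <- sign(m1[ne] - m2[ne]) * Inf; p[ne] <- 0
  }
  list(statistic = t, df = df, p_value = p)
}

#' Score every feature for risk-vs-benign discrimination
#'
#' Continuous (read or score) columns are tested with a two-sided Welch
#' t-test; binary (peak) columns with Fisher's exact test. A constant column
#' yields `p = 1` with a warning, never an abort. The direction is `enriched`
#' when the risk mean (or risk in-peak rate) exceeds the benign one.
#'
#' @param x an `annotation_matrix` or plain numeric matrix (columns whose
#'   values are all 0/1 are then treated as binary).
#' @param labels character vector of `"risk"`/`"benign"`, one per row.
#' @return a `data.frame` (one row per feature): `track_id`, `test`,
#'   `statistic` (t, or log2 odds ratio with a Haldane 0.5 correction),
#'   `p_value`, `direction`, `selected` (`NA` until a threshold is applied).
#' @export
compute_feature_pvalues <- function(x, labels) {
  meta <- if (inherits(x, "annotation_matrix")) x$col_meta else NULL
  xm <- as.matrix(x)
  stopifnot(length(labels) == nrow(xm))
  risk <- which(labels == "risk"); benign <- which(labels == "benign")
  if (!length(risk) || !length(benign)) stopf("both classes must be present")
  is_binary <- if (!is.null(meta)) meta$representation == "peak"
               else apply(xm, 2L, function(col) all(col %in% c(0, 1)))
  res <- data.frame(track_id = colnames(xm),
                    test = ifelse(is_binary, "fisher", "t"),
                    statistic = NA_real_, p_value = NA_real_,
                    direction = NA_character_, selected = NA,
                    stringsAsFactors = FALSE)
  cm <- colMeans(xm)
  const <- colSums((xm - rep(cm, each = nrow(xm)))^2) == 0
  if (any(const)) {
    warnf("%d constant feature column(s); p = 1 recorded", sum(const))
    res$statistic[const] <- 0
    res$p_value[const] <- 1
    res$direction[const] <- "enriched"
  }
  cont <- which(!is_binary & !const)
  if (length(cont)) {
    wt <- welch_t_cols(xm[, cont, drop = FALSE], risk, benign)
    res$statistic[cont] <- wt$statistic
    res$p_value[cont] <- wt$p_value
    res$direction[cont] <- ifelse(wt$statistic > 0, "enriched", "depleted")
  }
  bin <- which(is_binary & !const)
  for (j in bin) {
    a <- sum(xm[risk, j] == 1); b <- length(risk) - a
    c_ <- sum(xm[benign, j] == 1); d <- length(benign) - c_
    res$p_value[j] <- feature_pvalue_binary(a, b, c_, d)
    res$statistic[j] <- log2(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)))
    res$direction[j] <- if (a / length(risk) > c_ / length(benign)) "enriched" else "depleted"
  }
  res
}

#' Mark features selected at a p-value threshold
#'
#' @param pvalues result of [compute_feature_pvalues()].
#' @param threshold p-value cutoff; features with `p_value < threshold` are
#'   selected.
#' @return the table with `selected` filled in and the threshold attached as
#'   attribute `"threshold"`.
#' @export
apply_threshold <- function(pvalues, threshold) {
  pvalues$selected <- pvalues$p_value < threshold
  attr(pvalues, "threshold") <- threshold
  pvalues
}

#' Write or read a feature-selection table
#'
#' TSV columns: `track_id test statistic p_value direction selected`.
#'
#' @param pvalues feature-selection `data.frame`.
#' @param path file path.
#' @export
write_selection <- function(pvalues, path) {
  utils::write.table(pvalues, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# stratified fold assignment, seeded, stratified on label only
make_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, for (cl in unique(labels)) {
    i <- which(labels == cl)
    if (length(i) < k) stopf("class '%s' has %d members, fewer than k = %d folds", cl, length(i), k)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  })
  fold
}

#' Tune the feature-selection p-value threshold by cross-validation
#'
#' For each candidate threshold, stratified k-fold cross-validation is run on
#' the supplied data: within each fold, feature p-values are recomputed on the
#' training part only (so held-out rows never influence selection), features
#' below the threshold are kept, a balanced bagging ensemble is trained and
#' the held-out fold scored by AUC. The chosen threshold maximizes the mean
#' fold AUC; ties go to the smallest threshold. A (threshold, fold) pair that
#' selects zero features scores AUC 0.5 with a warning.
#'
#' @inheritParams compute_feature_pvalues
#' @param grid candidate p-value thresholds (default 0.01..0.20 step 0.01).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param base_kind base learner (`"tree"`, `"svm_radial"`, `"lasso"`).
#' @param C number of base learners; `NULL` uses the default rule per fold.
#' @return an object of class `threshold_cv`: list with `threshold`, `grid`,
#'   `mean_auc`, and the `fold_auc` matrix (grid x folds).
#' @export
select_threshold_cv <- function(x, labels, grid = seq(0.01, 0.20, by = 0.01),
                                k = 5L, seed = 1L, base_kind = "tree", C = NULL) {
  stopifnot(length(grid) >= 1)
  grid <- sort(grid)
  xm <- as.matrix(x)
  meta <- if (inherits(x, "annotation_matrix")) x$col_meta else NULL
  fold <- make_folds(labels, k, derive_seed(seed, "threshold_cv_folds"))
  fold_auc <- matrix(NA_real_, length(grid), k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    xtr <- if (is.null(meta)) xm[tr, , drop = FALSE] else x[tr, ]
    pv <- suppressWarnings(compute_feature_pvalues(xtr, labels[tr]))
    for (g in seq_along(grid)) {
      sel <- which(pv$p_value < grid[g])
      if (!length(sel)) {
        warnf("threshold %g selects no features in fold %d; AUC 0.5 recorded", grid[g], f)
        fold_auc[g, f] <- 0.5
        next
      }
      fit <- train_ensemble(xm[tr, sel, drop = FALSE], labels[tr],
                            base_kind = base_kind, C = C,
                            seed = derive_seed(seed, sprintf("thrcv_f%d_g%d", f, g)))
      sc <- predict_ensemble(fit, xm[te, sel, drop = FALSE])
      fold_auc[g, f] <- roc_auc(sc, labels[te])$auc
    }
  }
  mean_auc <- rowMeans(fold_auc)
  best <- which(mean_auc == max(mean_auc))[1L]  # grid sorted: ties -> smallest
  structure(list(threshold = grid[best], grid = grid, mean_auc = mean_auc,
                 fold_auc = fold_auc), class = "threshold_cv")
}

#' @export
print.threshold_cv <- function(x, ...) {
  cat(sprintf("<threshold_cv> chosen p-value threshold %g (mean CV-AUC %.3f over %d candidates)\n",
              x$threshold, max(x$mean_auc), length(x$grid)))
  invisible(x)
}
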