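#' ROC curve and AUC
#'
#' The AUC is computed by the Mann-Whitney rank formulation: the probability
#' that a random risk variant outscores a random benign one, counting ties as
#' one half. ROC (and precision-recall) points are swept over the unique
#' scores, so the trapezoidal area of the returned curve equals the rank AUC
#' exactly.
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels `"risk"`/`"benign"` per score.
#' @return a list with `auc`, `roc_points` (`fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `pr_points` (`recall`, `precision`).
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "risk"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- pos[o]
  grp <- !duplicated(s)
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(which(grp[-1L]) , length(s))  # last index of each tie group
  roc <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  pr <- data.frame(recall = tp[last] / n1,
                   precision = tp[last] / (tp[last] + fp[last]))
  list(auc = auc, roc_points = roc, pr_points = pr)
}

#' Matthews correlation coefficient at a score cutoff
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention that a zero factor in the denominator gives 0. Variants scoring
#' at or above the cutoff are called risk.
#'
#' @param scores numeric scores.
#' @param labels `"risk"`/`"benign"` per score.
#' @param cutoff score cutoff (default 0.5, the natural cutoff for ensemble
#'   probabilities).
#' @return a value in `[-1, 1]`.
#' @export
mcc <- function(scores, labels, cutoff = 0.5) {
  pos <- labels == "risk"
  call <- scores >= cutoff
  tp <- sum(call & pos); fp <- sum(call & !pos)
  tn <- sum(!call & !pos); fn <- sum(!call & pos)
  den <- sqrt(as.numeric(tp + fp) * (tp + fn)) * sqrt(as.numeric(tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Within each training fold the complete procedure is re-run from scratch:
#' feature p-values, threshold tuning (unless `threshold` is fixed), feature
#' selection and ensemble training all use only the training rows; the
#' held-out fold is then scored. Held-out rows therefore never influence
#' selection or fitting. Per-fold AUC and MCC are reported along with a
#' pooled ROC over the concatenated held-out scores.
#'
#' @inheritParams epirisk
#' @param k number of folds (default 5); each class must have >= k members.
#' @return an object of class `cv_result`: per-fold metrics (`fold_auc`,
#'   `fold_mcc`, `fold_threshold`), their mean and sd, pooled `auc` and
#'   `roc_points`, held-out `scores`, the `fold` assignment and, per fold,
#'   the training row indices (`train_index`) and selected features
#'   (`selected`).
#' @export
cross_validate <- function(x, labels, k = 5L, base_kind = "tree",
                           threshold = NULL, grid = seq(0.01, 0.20, by = 0.01),
                           C = NULL, seed = 1L) {
  xm <- as.matrix(x)
  # k = n is plain leave-one-out: singleton folds, no stratification possible
  fold <- if (k == length(labels)) seq_along(labels)
          else make_folds(labels, k, derive_seed(seed, "cv_folds"))
  scores <- rep(NA_real_, length(labels))
  fold_auc <- fold_mcc <- fold_thr <- rep(NA_real_, k)
  train_index <- selected <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    xtr <- if (inherits(x, "annotation_matrix")) x[tr, ] else xm[tr, , drop = FALSE]
    fit <- suppressWarnings(
      epirisk(xtr, labels[tr], base_kind = base_kind, threshold = threshold,
              grid = grid, C = C, k = min(k, 5L),
              seed = derive_seed(seed, sprintf("cv_fold%d", f))))
    sc <- predict(fit, xm[te, , drop = FALSE])
    scores[te] <- sc
    if (length(unique(labels[te])) == 2L) {
      fold_auc[f] <- roc_auc(sc, labels[te])$auc
      fold_mcc[f] <- mcc(sc, labels[te])
    }
    fold_thr[f] <- fit$threshold
    train_index[[f]] <- tr
    selected[[f]] <- fit$selected_features
  }
  pooled <- roc_auc(scores, labels)
  structure(list(fold_auc = fold_auc, fold_mcc = fold_mcc,
                 fold_threshold = fold_thr,
                 mean_auc = mean(fold_auc, na.rm = TRUE),
                 sd_auc = stats::sd(fold_auc[!is.na(fold_auc)]),
                 auc = pooled$auc, roc_points = pooled$roc_points,
                 pr_points = pooled$pr_points, scores = scores, fold = fold,
                 train_index = train_index, selected = selected, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: mean AUC %.3f (sd %.3f), pooled AUC %.3f\n",
              x$k, x$mean_auc, x$sd_auc, x$auc))
  cat(sprintf("  per-fold AUC: %s\n", paste(sprintf("%.3f", x$fold_auc), collapse = " ")))
  invisible(x)
}

#' Repeated independent test with resampled benign sets
#'
#' The model is trained once (pass a fitted `epirisk` object); for each
#' repeat, `ratio` times as many benign variants as test risk variants are
#' sampled from the benign pool (without replacement within a repeat), the
#' combined set is scored and an AUC computed. The mean and sd over repeats
#' absorb the sampling variability of the control set.
#'
#' @param object a fitted `epirisk` model.
#' @param test_risk numeric matrix of test risk-variant features (rows
#'   disjoint from the training set, e.g. after [exclude_within()]).
#' @param benign_pool numeric matrix of candidate benign features.
#' @param repeats number of benign resamples (default 10).
#' @param ratio benign-to-risk ratio per repeat (default 10).
#' @param seed integer seed.
#' @return a list with `mean_auc`, `sd_auc` (0 when `repeats = 1`) and the
#'   per-repeat `auc` vector.
#' @export
independent_test <- function(object, test_risk, benign_pool, repeats = 10L,
                             ratio = 10L, seed = 1L) {
  stopifnot(inherits(object, "epirisk"))
  n_b <- ratio * nrow(test_risk)
  if (nrow(benign_pool) < n_b)
    stopf("benign pool has %d rows; %d needed per repeat", nrow(benign_pool), n_b)
  auc <- vapply(seq_len(repeats), function(r) {
    idx <- with_seed(derive_seed(seed, sprintf("repeat%d", r)),
                     sample(nrow(benign_pool), n_b))
    xte <- rbind(test_risk, benign_pool[idx, , drop = FALSE])
    yte <- c(rep("risk", nrow(test_risk)), rep("benign", n_b))
    roc_auc(predict(object, xte), yte)$auc
  }, numeric(1))
  list(mean_auc = mean(auc), sd_auc = if (repeats > 1L) stats::sd(auc) else 0,
       auc = auc)
}

#' Leave-one-disease-out evaluation within a disease class
#'
#' For each disease, a model is trained on the pooled risk and matched benign
#' variants of all the other diseases and evaluated on the held-out disease's
#' variants, probing whether risk variants of phenotypically related diseases
#' share an epigenomic signature.
#'
#' @inheritParams epirisk
#' @param diseases disease tag per row of `x` (both the risk variants and
#'   their matched benign controls carry their disease's tag).
#' @return a `data.frame` with one row per disease: `disease`, `auc`,
#'   `n_risk`, `n_benign`.
#' @export
leave_one_disease_out <- function(x, labels, diseases, base_kind = "tree",
                                  threshold = NULL,
                                  grid = seq(0.01, 0.20, by = 0.01),
                                  C = NULL, seed = 1L) {
  ds <- unique(diseases)
  if (length(ds) < 2L) stopf("leave-one-disease-out needs >= 2 diseases")
  xm <- as.matrix(x)
  out <- lapply(ds, function(d) {
    tr <- which(diseases != d); te <- which(diseases == d)
    xtr <- if (inherits(x, "annotation_matrix")) x[tr, ] else xm[tr, , drop = FALSE]
    fit <- suppressWarnings(
      epirisk(xtr, labels[tr], base_kind = base_kind, threshold = threshold,
              grid = grid, C = C, seed = derive_seed(seed, paste0("lodo_", d))))
    sc <- predict(fit, xm[te, , drop = FALSE])
    data.frame(disease = d, auc = roc_auc(sc, labels[te])$auc,
               n_risk = sum(labels[te] == "risk"),
               n_benign = sum(labels[te] == "benign"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write an evaluation report
#'
#' Per-fold (or per-repeat) metrics as TSV, with optional ROC/PR point files
#' alongside (`<path>.roc.tsv`, `<path>.pr.tsv`).
#'
#' @param cv a `cv_result`.
#' @param path output TSV.
#' @param points also write pooled ROC and PR points (default TRUE).
#' @export
write_evaluation <- function(cv, path, points = TRUE) {
  d <- data.frame(fold = seq_len(cv$k), auc = cv$fold_auc, mcc = cv$fold_mcc,
                  threshold = cv$fold_threshold)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (points) {
    utils::write.table(cv$roc_points, paste0(path, ".roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cv$pr_points, paste0(path, ".pr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
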