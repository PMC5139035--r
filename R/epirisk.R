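#' Fit a disease-specific variant prioritization model
#'
#' The central fitting function. Given an annotation matrix (variants by
#' epigenomic features) with class labels, it (1) scores every feature for
#' risk-vs-benign discrimination (Welch t-test for continuous columns,
#' Fisher's exact test for binary peak columns), (2) selects informative
#' features at a p-value threshold tuned by stratified cross-validation
#' unless a threshold is supplied, and (3) trains a balanced bagging ensemble
#' of base classifiers on the selected features, resampling the benign class
#' to correct the risk/benign imbalance. The score of a variant is the mean
#' of the base-learner probabilities that it is disease-implicated.
#'
#' @param x an `annotation_matrix` (see [build_annotation_matrix()]) or a
#'   plain numeric matrix with column names.
#' @param labels character vector of `"risk"`/`"benign"`, one per row of `x`.
#' @param base_kind base learner: `"tree"` (default), `"svm_radial"` or
#'   `"lasso"`.
#' @param threshold feature-selection p-value cutoff; `NULL` (default) tunes
#'   it on `grid` by k-fold cross-validation via [select_threshold_cv()].
#' @param grid candidate thresholds for tuning.
#' @param C ensemble size; `NULL` uses `ceiling(2 * n_benign / n_risk)`.
#' @param k folds for threshold tuning.
#' @param seed integer seed governing all randomness in the fit.
#' @param disease optional disease tag stored with the model.
#' @return an object of class `epirisk` with components `pvalues` (the
#'   feature-selection table), `threshold`, `threshold_cv` (tuning trace or
#'   `NULL`), `selected_features`, `ensemble` (the fitted `risk_ensemble`),
#'   `fitted.values` (training-set scores), `labels`, `seed`, `disease` and
#'   `call`. Methods: `print`, `summary`, `predict`, `coef`, `plot`,
#'   `residuals`.
#' @examples
#' sim <- simulate_annotation(n_risk = 30, n_benign = 150, n_features = 40,
#'                            n_informative = 8, fold = 4, seed = 1)
#' fit <- epirisk(sim$x, sim$labels, threshold = 0.05, seed = 1)
#' summary(fit)
#' head(predict(fit, sim$x))
#' @export
epirisk <- function(x, labels, base_kind = "tree", threshold = NULL,
                    grid = seq(0.01, 0.20, by = 0.01), C = NULL, k = 5L,
                    seed = 1L, disease = NA_character_) {
  cl <- match.call()
  xm <- as.matrix(x)
  stopifnot(length(labels) == nrow(xm))
  pv <- compute_feature_pvalues(x, labels)
  tcv <- NULL
  if (is.null(threshold)) {
    tcv <- select_threshold_cv(x, labels, grid = grid, k = k,
                               seed = derive_seed(seed, "threshold"),
                               base_kind = base_kind, C = C)
    threshold <- tcv$threshold
  }
  pv <- apply_threshold(pv, threshold)
  sel <- pv$track_id[pv$selected]
  if (!length(sel))
    stopf("no features pass p < %g: relax the selection threshold", threshold)
  ens <- train_ensemble(xm[, sel, drop = FALSE], labels, base_kind = base_kind,
                        C = C, seed = derive_seed(seed, "ensemble"))
  fitted <- predict_ensemble(ens, xm)
  names(fitted) <- rownames(xm)
  structure(list(pvalues = pv, threshold = threshold, threshold_cv = tcv,
                 selected_features = sel, ensemble = ens,
                 fitted.values = fitted, labels = labels,
                 base_kind = base_kind, seed = as.integer(seed),
                 disease = disease, call = cl),
            class = "epirisk")
}

#' @export
print.epirisk <- function(x, ...) {
  cat("Disease-specific variant prioritization model\n")
  if (!is.na(x$disease)) cat(sprintf("  disease: %s\n", x$disease))
  cat(sprintf("  training: %d risk / %d benign variants\n",
              sum(x$labels == "risk"), sum(x$labels == "benign")))
  cat(sprintf("  features: %d of %d selected at p < %g%s\n",
              length(x$selected_features), nrow(x$pvalues), x$threshold,
              if (is.null(x$threshold_cv)) "" else " (CV-tuned)"))
  cat(sprintf("  ensemble: %d %s learner(s)\n", x$ensemble$C, x$base_kind))
  invisible(x)
}

#' @export
summary.epirisk <- function(object, n_top = 10L, ...) {
  pv <- object$pvalues[order(object$pvalues$p_value), ]
  tr_auc <- roc_auc(object$fitted.values, object$labels)$auc
  structure(list(fit = object, top = utils::head(pv, n_top),
                 training_auc = tr_auc,
                 n_enriched = sum(pv$selected & pv$direction == "enriched"),
                 n_depleted = sum(pv$selected & pv$direction == "depleted")),
            class = "summary.epirisk")
}

#' @export
print.summary.epirisk <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  selected: %d enriched, %d depleted in risk variants\n",
              x$n_enriched, x$n_depleted))
  cat(sprintf("  training-set AUC (resubstitution, optimistic): %.3f\n", x$training_auc))
  cat("\nTop features by p-value:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Score new variants with a fitted model
#'
#' @param object an `epirisk` fit.
#' @param newdata an `annotation_matrix` or numeric matrix carrying (at
#'   least) the model's selected feature columns; omitting it returns the
#'   training-set scores.
#' @param ... ignored.
#' @return risk probabilities in `[0, 1]`, named by variant id.
#' @export
predict.epirisk <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  xm <- as.matrix(newdata)
  p <- predict_ensemble(object$ensemble, xm)
  names(p) <- rownames(xm)
  p
}

#' Feature weights of a fitted model
#'
#' For the lasso base learner, the per-feature logistic coefficients averaged
#' over the ensemble; for the tree learner, the Gini impurity importance
#' accumulated over the ensemble's trees. The radial SVM has no per-feature
#' coefficients and returns `NULL` with a message.
#'
#' @param object an `epirisk` fit.
#' @param ... ignored.
#' @export
coef.epirisk <- function(object, ...) {
  feats <- object$ensemble$feature_names
  if (object$base_kind == "lasso") {
    M <- vapply(object$ensemble$learners, function(l) {
      cf <- as.matrix(stats::coef(l, s = "lambda.min"))[, 1L]
      full <- stats::setNames(numeric(length(feats)), feats)
      hit <- intersect(names(cf), feats)
      full[hit] <- cf[hit]
      full
    }, numeric(length(feats)))
    return(rowMeans(M))
  }
  if (object$base_kind == "tree") {
    imp <- object$ensemble$forest$variable.importance
    full <- stats::setNames(numeric(length(feats)), feats)
    full[names(imp)] <- imp
    return(full)
  }
  message("radial-kernel SVM learners have no per-feature coefficients")
  NULL
}

#' Residuals of a fitted model
#'
#' Response residuals on the training set: the 0/1 class indicator (risk = 1)
#' minus the fitted ensemble probability.
#'
#' @param object an `epirisk` fit.
#' @param ... ignored.
#' @export
residuals.epirisk <- function(object, ...) {
  as.numeric(object$labels == "risk") - object$fitted.values
}

#' Plot the feature screen of a fitted model
#'
#' Histogram of the per-feature p-values with the selection threshold marked;
#' informative (selected) features fall left of the line.
#'
#' @param x an `epirisk` fit.
#' @param ... passed to `hist`.
#' @export
plot.epirisk <- function(x, ...) {
  graphics::hist(x$pvalues$p_value, breaks = 40, col = "grey85",
                 main = "Feature screen", xlab = "p-value", ...)
  graphics::abline(v = x$threshold, col = "red3", lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("threshold %g (%d selected)", x$threshold,
                                    length(x$selected_features)))
  invisible(x)
}

#' Save or load a fitted model archive
#'
#' The archive is a directory holding a versioned plain-text metadata file
#' (`metadata.yaml`: base kind, ensemble size, threshold, seeds, selected
#' features in order), the feature-selection table (`selection.tsv`), and the
#' fitted learner parameters (`learners.rds`). A round-trip restores a model
#' whose predictions are identical to the original's.
#'
#' @param object an `epirisk` fit.
#' @param dir archive directory (created if needed).
#' @export
save_model <- function(object, dir) {
  stopifnot(inherits(object, "epirisk"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = 1L, base_kind = object$base_kind,
               C = object$ensemble$C, threshold = object$threshold,
               seed = object$seed, disease = as.character(object$disease),
               resample_seeds = object$ensemble$resample_seeds,
               selected_features = object$selected_features)
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  write_selection(object$pvalues, file.path(dir, "selection.tsv"))
  saveRDS(object, file.path(dir, "learners.rds"), version = 2L)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  obj <- readRDS(file.path(dir, "learners.rds"))
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  if (!identical(as.integer(meta$format_version), 1L))
    stopf("unsupported model archive version: %s", meta$format_version)
  stopifnot(identical(meta$selected_features, obj$selected_features))
  obj
}

#' Write per-variant scores as TSV
#'
#' Columns: `id chrom pos score`.
#'
#' @param variants variant table scored.
#' @param scores numeric scores aligned with `variants` rows.
#' @param path output TSV.
#' @export
write_scores <- function(variants, scores, path) {
  d <- data.frame(id = variants$id, chrom = variants$chrom, pos = variants$pos,
                  score = scores, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
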