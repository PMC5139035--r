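#' Default number of base learners
#'
#' The ensemble size defaults to twice the benign-to-risk ratio,
#' `ceiling(2 * n_benign / n_risk)`, chosen so the union of the benign
#' resamples covers most of the benign set. At the standard 10:1 design this
#' gives 20 learners.
#'
#' @param n_benign,n_risk class sizes.
#' @return an integer ensemble size.
#' @export
default_num_learners <- function(n_benign, n_risk) {
  if (n_risk < 1) stopf("n_risk must be >= 1")
  as.integer(ceiling(2 * n_benign / n_risk))
}

.class_levels <- c("benign", "risk")

#' Base learner factory
#'
#' Returns a base binary classifier honoring a two-function contract:
#' `fit(x, y)` (numeric matrix, labels `"risk"`/`"benign"`, trained on
#' exactly the rows given) and `probability(model, x)` (probability of class
#' risk). Kinds:
#' \describe{
#'   \item{tree}{a single CART-style decision tree (`ranger`, one unpruned
#'     tree): Gini impurity, no depth cap, minimum leaf size 5, all features
#'     considered at every split; leaf class frequencies give the
#'     probabilities.}
#'   \item{svm_radial}{radial-kernel SVM (`e1071`) with Platt-style sigmoid
#'     probabilities fit on its own training set.}
#'   \item{lasso}{L1-penalized logistic regression (`glmnet`), penalty tuned
#'     by fivefold cross-validation on its balanced training set.}
#' }
#'
#' @param kind `"tree"`, `"svm_radial"` or `"lasso"`.
#' @param seed integer seed for the learner's internal randomness.
#' @param min_leaf minimum leaf size for the tree learner.
#' @return a list with elements `kind`, `fit` and `probability`.
#' @export
base_learner_factory <- function(kind = c("tree", "svm_radial", "lasso"),
                                 seed = 1L, min_leaf = 5L) {
  kind <- match.arg(kind)
  if (kind == "tree") {
    return(list(kind = kind,
      fit = function(x, y) {
        ranger::ranger(x = x, y = base::factor(y, levels = .class_levels),
                       probability = TRUE, num.trees = 1L, mtry = ncol(x),
                       min.node.size = min_leaf, replace = FALSE,
                       sample.fraction = 1, num.threads = 1L, seed = seed)
      },
      probability = function(model, x) {
        unname(stats::predict(model, x, num.threads = 1L)$predictions[, "risk"])
      }))
  }
  if (kind == "svm_radial") {
    return(list(kind = kind,
      fit = function(x, y) {
        with_seed(seed,
          e1071::svm(x, base::factor(y, levels = .class_levels),
                     kernel = "radial", probability = TRUE))
      },
      probability = function(model, x) {
        pr <- stats::predict(model, x, probability = TRUE)
        unname(attr(pr, "probabilities")[, "risk"])
      }))
  }
  list(kind = kind,
    fit = function(x, y) {
      if (ncol(x) < 2L) x <- cbind(x, .const = 0)  # glmnet needs >= 2 columns
      with_seed(seed,
        glmnet::cv.glmnet(x, base::factor(y, levels = .class_levels),
                          family = "binomial", alpha = 1, nfolds = 5L))
    },
    probability = function(model, x) {
      if (ncol(x) < 2L) x <- cbind(x, .const = 0)
      as.numeric(stats::predict(model, x, s = "lambda.min", type = "response"))
    })
}

#' Train a balanced bagging ensemble
#'
#' Builds `C` balanced training sets by resampling, for each base learner,
#' as many benign variants (with replacement) as there are risk variants; the
#' learner is fit on the union of the resample and the full risk set. Every
#' learner's training set is exactly class-balanced (asserted at fit time).
#' Each learner's benign-resample seed is stored, so the fitted ensemble is
#' reproducible bit for bit from `(x, labels, seed, config)`.
#'
#' For the default tree learner the `C` trees are grown in one `ranger`
#' forest whose per-tree in-bag counts encode exactly these balanced
#' resamples (all risk variants once, the benign resample with its
#' multiplicities); probability averaging over learners is still done
#' explicitly by [predict_ensemble()]. SVM and lasso learners are fit one by
#' one.
#'
#' @param x numeric matrix restricted to the selected features.
#' @param labels `"risk"`/`"benign"` per row.
#' @param base_kind base learner kind (see [base_learner_factory()]).
#' @param C ensemble size; `NULL` uses [default_num_learners()].
#' @param seed integer seed.
#' @return an object of class `risk_ensemble`.
#' @export
train_ensemble <- function(x, labels, base_kind = "tree", C = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) stopf("empty feature set: relax the selection threshold")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  risk <- which(labels == "risk"); benign <- which(labels == "benign")
  if (!length(risk) || !length(benign)) stopf("both classes must be present")
  if (is.null(C)) C <- default_num_learners(length(benign), length(risk))
  stopifnot(C >= 1L)
  resample_seeds <- with_seed(derive_seed(seed, "resample_seeds"),
                              sample.int(2^30, C))
  resamples <- lapply(resample_seeds, function(s)
    with_seed(s, sample(benign, length(risk), replace = TRUE)))
  obj <- list(base_kind = base_kind, C = as.integer(C),
              resample_seeds = resample_seeds, resamples = resamples,
              feature_names = colnames(x),
              n_risk = length(risk), n_benign = length(benign),
              seed = as.integer(seed))
  if (base_kind == "tree") {
    inbag <- lapply(resamples, function(ni) {
      cnt <- integer(nrow(x))
      cnt[risk] <- 1L
      tab <- tabulate(ni, nbins = nrow(x))
      cnt[benign] <- tab[benign]
      stopifnot(sum(cnt[risk]) == sum(cnt[benign]))  # balanced by construction
      cnt
    })
    rf <- ranger::ranger(x = x, y = base::factor(labels, levels = .class_levels),
                         probability = TRUE, num.trees = C, mtry = ncol(x),
                         min.node.size = 5L, inbag = inbag,
                         importance = "impurity", num.threads = 1L,
                         seed = derive_seed(seed, "forest"))
    obj$engine <- "ranger_batched"
    obj$forest <- rf
  } else {
    obj$engine <- "loop"
    obj$learners <- vector("list", C)
    for (i in seq_len(C)) {
      idx <- c(risk, resamples[[i]])
      yb <- labels[idx]
      stopifnot(sum(yb == "risk") == sum(yb == "benign"))
      bl <- base_learner_factory(base_kind, seed = derive_seed(resample_seeds[i], "fit"))
      obj$learners[[i]] <- bl$fit(x[idx, , drop = FALSE], yb)
    }
  }
  structure(obj, class = "risk_ensemble")
}

#' Per-learner risk probabilities
#'
#' The probability of class risk from each stored base learner separately,
#' before averaging; column i belongs to learner i.
#'
#' @param model a `risk_ensemble`.
#' @param x numeric matrix containing the model's feature columns.
#' @return a numeric matrix, rows = variants, columns = learners.
#' @export
learner_probabilities <- function(model, x) {
  x <- as.matrix(x)
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss)) stopf("missing feature column(s): %s", paste(miss, collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  if (model$engine == "ranger_batched") {
    pr <- stats::predict(model$forest, x, predict.all = TRUE,
                         num.threads = 1L)$predictions
    risk_col <- match("risk", colnames(stats::predict(
      model$forest, x[1L, , drop = FALSE], num.threads = 1L)$predictions))
    m <- pr[, risk_col, , drop = FALSE]
    dim(m) <- c(nrow(x), model$C)
    return(m)
  }
  bl <- base_learner_factory(model$base_kind)
  matrix(vapply(model$learners, function(l) bl$probability(l, x),
                numeric(nrow(x))), nrow = nrow(x))
}

#' Ensemble risk probability
#'
#' The probability that a variant is disease-implicated is the average of the
#' base learners' predictive probabilities.
#'
#' @param model a `risk_ensemble`.
#' @param x numeric matrix containing at least the model's selected feature
#'   columns (used in stored order).
#' @return a numeric vector of probabilities in `[0, 1]`.
#' @export
predict_ensemble <- function(model, x) {
  p <- learner_probabilities(model, x)
  unname(rowMeans(p))
}

#' @export
print.risk_ensemble <- function(x, ...) {
  cat(sprintf("<risk_ensemble> %d %s learner(s) on %d feature(s); %d risk / %d benign\n",
              x$C, x$base_kind, length(x$feature_names), x$n_risk, x$n_benign))
  invisible(x)
}
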