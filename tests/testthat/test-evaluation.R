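test_that("AUC equals brute-force pair counting, with the tie convention", {
  lab8 <- rep(c("risk", "benign"), each = 4)
  set.seed(3)
  for (i in 1:25) {
    s <- sample(100, 8)  # all distinct
    expect_equal(roc_auc(s, lab8)$auc, auc_pairs(s, lab8))
  }
  expect_equal(roc_auc(c(9, 8, 2, 1), c("risk", "risk", "benign", "benign"))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c("risk", "benign"), 5))$auc, 0.5)
  with_ties <- c(1, 1, 1, 0, 0, 1)
  lab6 <- c("risk", "risk", "benign", "benign", "risk", "benign")
  expect_equal(roc_auc(with_ties, lab6)$auc, auc_pairs(with_ties, lab6))
  expect_error(roc_auc(1:3, rep("risk", 3)), "both classes")
})

test_that("ROC endpoints and trapezoidal area are consistent with the rank AUC", {
  set.seed(5)
  s <- c(rnorm(30, 1), rnorm(60)); lab <- rep(c("risk", "benign"), c(30, 60))
  r <- roc_auc(s, lab)
  expect_equal(r$roc_points$fpr[1], 0); expect_equal(r$roc_points$tpr[1], 0)
  expect_equal(tail(r$roc_points$fpr, 1), 1); expect_equal(tail(r$roc_points$tpr, 1), 1)
  trap <- with(r$roc_points, sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2))
  expect_equal(trap, r$auc, tolerance = 1e-12)
  # invariance under strictly monotone transforms; complement rule when no ties
  expect_equal(roc_auc(qlogis(plogis(s)), lab)$auc, r$auc)
  expect_equal(roc_auc(exp(s), lab)$auc, r$auc)
  expect_equal(roc_auc(-s, lab)$auc, 1 - r$auc)
  skip_if_not_installed("pROC")
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(lab, s, levels = c("benign", "risk"),
                                              direction = "<", quiet = TRUE))))
})

test_that("MCC follows the confusion-matrix formula with the zero convention", {
  lab <- rep(c("risk", "benign"), c(5, 5))
  expect_equal(mcc(c(rep(0.9, 5), rep(0.1, 5)), lab), 1)
  expect_equal(mcc(c(rep(0.1, 5), rep(0.9, 5)), lab), -1)
  tp <- 90; fp <- 10; tn <- 95; fn <- 5
  s <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
  l <- c(rep("risk", tp + fn), rep("benign", fp + tn))
  direct <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn)) / sqrt((tn + fp) * (tn + fn))
  expect_equal(mcc(s, l), direct)
  expect_equal(mcc(rep(1, 10), lab), 0)  # empty negative margin
})

test_that("cross-validation never leaks held-out rows and handles leave-one-out", {
  sim <- simulate_annotation(n_risk = 30, n_benign = 150, n_features = 40,
                             n_informative = 10, fold = 4, seed = 21)
  cv <- suppressWarnings(cross_validate(sim$x, sim$labels, k = 5,
                                        threshold = 0.05, seed = 21))
  for (f in 1:5) {
    expect_length(intersect(cv$train_index[[f]], which(cv$fold == f)), 0L)
    expect_setequal(c(cv$train_index[[f]], which(cv$fold == f)),
                    seq_along(sim$labels))
  }
  expect_true(all(!is.na(cv$scores)))
  expect_gte(cv$mean_auc, 0.8)
  tf <- tempfile(fileext = ".tsv")
  write_evaluation(cv, tf)
  expect_equal(nrow(read.delim(tf)), 5L)
  expect_true(file.exists(paste0(tf, ".roc.tsv")))

  toy <- simulate_annotation(n_risk = 10, n_benign = 10, n_features = 8,
                             n_informative = 4, fold = 5, seed = 22)
  loo <- suppressWarnings(cross_validate(toy$x, toy$labels, k = 20,
                                         threshold = 0.2, C = 3, seed = 1))
  expect_length(loo$scores, 20L)
  expect_true(all(!is.na(loo$scores)))
  expect_error(cross_validate(toy$x, toy$labels, k = 15, threshold = 0.2),
               "fewer than")
})

test_that("repeated independent testing averages over benign resamples", {
  # one generative draw, split into train and held-out rows so the planted
  # feature identities are shared
  sim_all <- simulate_annotation(n_risk = 65, n_benign = 600, n_features = 50,
                                 n_informative = 15, fold = 3, seed = 25)
  x_all <- as.matrix(sim_all$x)
  risk_rows <- which(sim_all$labels == "risk")
  ben_rows <- which(sim_all$labels == "benign")
  tr_rows <- c(risk_rows[1:40], ben_rows[1:200])
  fit <- epirisk(x_all[tr_rows, ], sim_all$labels[tr_rows],
                 threshold = 0.05, seed = 25)
  xr <- x_all[risk_rows[41:65], ]
  xb <- x_all[ben_rows[201:600], ]
  it <- independent_test(fit, xr, xb, repeats = 10, ratio = 10, seed = 27)
  expect_length(it$auc, 10L)
  expect_gte(it$mean_auc, 0.8)
  one <- independent_test(fit, xr, xb, repeats = 1, seed = 28)
  expect_equal(one$sd_auc, 0)
  # a scorer fed identical rows for both classes is at chance exactly
  same <- xb[rep(1, 30), ]
  expect_equal(independent_test(fit, same[1:3, ], same, repeats = 2, ratio = 5,
                                seed = 29)$mean_auc, 0.5)
  expect_error(independent_test(fit, xr, xb[1:10, ], repeats = 2), "pool")
})

test_that("leave-one-disease-out transfers between exchangeable diseases and flips on inverted effects", {
  set.seed(33)
  n_feat <- 30; shift <- 3
  mk_disease <- function(tag, dir) {
    n_r <- 30; n_b <- 120
    x <- matrix(rnbinom((n_r + n_b) * n_feat, mu = 5, size = 2),
                n_r + n_b, n_feat)
    x[1:n_r, 1:8] <- rnbinom(n_r * 8, mu = 5 * ifelse(dir > 0, shift, 1 / shift),
                             size = 2)
    colnames(x) <- sprintf("trk%04d", 1:n_feat)
    rownames(x) <- sprintf("%s_%03d", tag, 1:(n_r + n_b))
    list(x = x, labels = rep(c("risk", "benign"), c(n_r, n_b)),
         diseases = rep(tag, n_r + n_b))
  }
  a <- mk_disease("dzA", +1); b <- mk_disease("dzB", +1)
  x <- rbind(a$x, b$x); labels <- c(a$labels, b$labels)
  diseases <- c(a$diseases, b$diseases)
  res <- leave_one_disease_out(x, labels, diseases, threshold = 0.05, seed = 40)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$disease, c("dzA", "dzB"))
  cvA <- suppressWarnings(cross_validate(a$x, a$labels, threshold = 0.05, seed = 41))
  expect_lt(abs(res$auc[res$disease == "dzA"] - cvA$mean_auc), 0.08)
  # a held-out disease with inverted feature effects scores below chance
  binv <- mk_disease("dzB", -1)
  xi <- rbind(a$x, binv$x)
  resi <- leave_one_disease_out(xi, labels, diseases, threshold = 0.05, seed = 42)
  expect_lt(resi$auc[resi$disease == "dzB"], 0.5)
  expect_error(leave_one_disease_out(a$x, a$labels, a$diseases), ">= 2")
})
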