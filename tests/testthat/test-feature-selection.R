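test_that("continuous feature test behaves like a two-sided Welch t-test", {
  x <- c(1, 2, 3, 4, 5)
  r <- feature_pvalue_continuous(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(feature_pvalue_continuous(1, x), ">= 2")
  # constant equal groups -> the degenerate convention
  expect_equal(feature_pvalue_continuous(rep(2, 5), rep(2, 9)),
               list(statistic = 0, p_value = 1))
  # a large shifted sample separates with t > 0, p ~ 0
  set.seed(1)
  b <- rnorm(500); a <- b[1:400] + 1
  r2 <- feature_pvalue_continuous(a, b)
  expect_gt(r2$statistic, 0)
  expect_lt(r2$p_value, 1e-10)
})

test_that("Welch p-value agrees with a permutation-test oracle", {
  set.seed(42)
  a <- rnbinom(20, mu = 8, size = 2); b <- rnbinom(20, mu = 5, size = 2)
  obs <- abs(feature_pvalue_continuous(a, b)$statistic)
  pool <- c(a, b)
  B <- 1e5
  set.seed(7)
  idx <- replicate(B, sample.int(40L, 20L))          # 20 x B permuted group-1 indices
  g1 <- matrix(pool[idx], 20L, B)
  s_all <- sum(pool); ss_all <- sum(pool^2)
  m1 <- colMeans(g1); m2 <- (s_all - colSums(g1)) / 20
  v1 <- (colSums(g1^2) - 20 * m1^2) / 19
  v2 <- ((ss_all - colSums(g1^2)) - 20 * m2^2) / 19
  t_perm <- abs(m1 - m2) / sqrt(v1 / 20 + v2 / 20)
  perm_p <- mean(t_perm >= obs - 1e-12)
  welch_p <- feature_pvalue_continuous(a, b)$p_value
  # agreement within Monte-Carlo error (3 binomial sd) plus the t-approximation slack
  tol <- 3 * sqrt(perm_p * (1 - perm_p) / B) + 0.25 * perm_p + 0.01
  expect_lt(abs(welch_p - perm_p), tol)
})

test_that("vectorized column t-tests match stats::t.test", {
  set.seed(23)
  x <- matrix(rnbinom(200 * 20, mu = 5, size = 2), 200, 20)
  labels <- sample(rep(c("risk", "benign"), c(40, 160)))
  wt <- epirisk:::welch_t_cols(x, which(labels == "risk"), which(labels == "benign"))
  for (j in sample(20, 8)) {
    ht <- t.test(x[labels == "risk", j], x[labels == "benign", j])
    expect_equal(wt$statistic[j], unname(ht$statistic), tolerance = 1e-10)
    expect_equal(wt$p_value[j], ht$p.value, tolerance = 1e-10)
  }
})

test_that("Fisher test matches full hypergeometric enumeration", {
  expect_equal(feature_pvalue_binary(5, 5, 5, 5), 1)
  expect_equal(feature_pvalue_binary(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(feature_pvalue_binary(1, 9, 11, 3), fisher_enum_p(1, 9, 11, 3),
               tolerance = 1e-9)
  set.seed(31)
  for (i in 1:50) {
    tab <- sample.int(16, 4) - 1L
    if (any(rowSums(matrix(tab, 2, byrow = TRUE)) == 0) ||
        any(colSums(matrix(tab, 2, byrow = TRUE)) == 0)) next
    p <- feature_pvalue_binary(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, fisher_enum_p(tab[1], tab[2], tab[3], tab[4]), tolerance = 1e-9)
    # transposition invariance
    expect_equal(p, feature_pvalue_binary(tab[1], tab[3], tab[2], tab[4]),
                 tolerance = 1e-12)
  }
  expect_error(feature_pvalue_binary(0, 0, 3, 4), "margin")
})

test_that("the feature screen routes columns to the right test", {
  set.seed(37)
  n <- 60
  labels <- rep(c("risk", "benign"), c(20, 40))
  xr <- matrix(rnbinom(n * 3, mu = 4, size = 2), n, 3)
  xb <- matrix(rbinom(n * 2, 1, 0.3), n, 2)
  xc <- matrix(5, n, 1)
  x <- cbind(xr, xb, xc)
  colnames(x) <- paste0("c", 1:6)
  meta <- data.frame(track_id = colnames(x), factor = "f", cell_line = "c",
                     source = "REMC",
                     category = "histone",
                     representation = c("read", "read", "read", "peak", "peak", "read"),
                     stringsAsFactors = FALSE)
  am <- annotation_matrix(x, meta)
  expect_warning(pv <- compute_feature_pvalues(am, labels), "constant")
  expect_equal(pv$test, c("t", "t", "t", "fisher", "fisher", "t"))
  expect_equal(pv$p_value[6], 1)
  # single-feature consistency with the scalar tests
  expect_equal(pv$p_value[1],
               feature_pvalue_continuous(x[labels == "risk", 1],
                                         x[labels == "benign", 1])$p_value)
  a <- sum(x[labels == "risk", 4]); b <- 20 - a
  c_ <- sum(x[labels == "benign", 4]); d <- 40 - c_
  expect_equal(pv$p_value[4], feature_pvalue_binary(a, b, c_, d))
  # all-constant matrix: everything p = 1, nothing selectable below 1
  xconst <- matrix(2, 30, 4, dimnames = list(NULL, paste0("k", 1:4)))
  expect_warning(pvc <- compute_feature_pvalues(xconst, rep(c("risk", "benign"), 15)))
  expect_true(all(pvc$p_value == 1))
  expect_true(!any(apply_threshold(pvc, 0.999)$selected))
})

test_that("planted features occupy the smallest p-value tail with correct direction", {
  sim <- simulate_annotation(n_risk = 50, n_benign = 500, n_features = 200,
                             n_informative = 20, fold = 3, seed = 8)
  pv <- compute_feature_pvalues(sim$x, sim$labels)
  top <- pv$track_id[order(pv$p_value)][1:30]
  expect_gte(sum(sim$truth$track_id %in% top), 16)  # >= 80% in the tail
  m <- merge(pv, sim$truth, by = "track_id")
  expect_gt(mean(m$direction.x == m$direction.y), 0.85)
})

test_that("selection is monotone in the threshold", {
  sim <- simulate_annotation(n_risk = 40, n_benign = 200, n_features = 100,
                             n_informative = 10, fold = 2, seed = 12)
  pv <- compute_feature_pvalues(sim$x, sim$labels)
  sel <- lapply(c(0.01, 0.05, 0.1, 0.2), function(th)
    pv$track_id[apply_threshold(pv, th)$selected])
  for (i in 1:3) expect_true(all(sel[[i]] %in% sel[[i + 1]]))
  tsv <- tempfile(fileext = ".tsv")
  write_selection(apply_threshold(pv, 0.05), tsv)
  expect_equal(read_selection(tsv)$selected, apply_threshold(pv, 0.05)$selected)
})

test_that("threshold tuning returns the sole grid value and recovers planted features", {
  sim <- simulate_annotation(n_risk = 40, n_benign = 200, n_features = 100,
                             n_informative = 15, fold = 3, seed = 16)
  one <- select_threshold_cv(sim$x, sim$labels, grid = 0.07, seed = 1)
  expect_equal(one$threshold, 0.07)
  hits <- 0L
  for (s in 1:5) {
    simi <- simulate_annotation(n_risk = 40, n_benign = 240, n_features = 150,
                                n_informative = 15, fold = 3, seed = 100 + s)
    thr <- suppressWarnings(select_threshold_cv(simi$x, simi$labels, seed = s))
    pv <- apply_threshold(compute_feature_pvalues(simi$x, simi$labels), thr$threshold)
    rec <- mean(simi$truth$track_id %in% pv$track_id[pv$selected])
    if (rec >= 0.8) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("pure-noise data tunes to chance-level fold AUCs on every grid value", {
  sim <- simulate_annotation(n_risk = 60, n_benign = 140, n_features = 20,
                             n_informative = 0, fold = 1, seed = 19)
  thr <- suppressWarnings(select_threshold_cv(sim$x, sim$labels, seed = 3))
  expect_true(all(abs(thr$mean_auc - 0.5) <= 0.12))
})
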