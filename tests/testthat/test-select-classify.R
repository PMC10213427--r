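# Two-Gaussian feature matrix with `n_inf` informative columns (group mean
# shift `delta` in z-units) and `n_noise` pure-noise columns.
gaussian_features <- function(n_per_group, n_inf, n_noise, delta, seed) {
  set.seed(seed)
  n <- 2L * n_per_group
  labels <- rep(c(1L, 0L), each = n_per_group)
  x <- matrix(rnorm(n * (n_inf + n_noise)), n)
  x[labels == 1L, seq_len(n_inf)] <- x[labels == 1L, seq_len(n_inf)] + delta
  colnames(x) <- paste0("F", seq_len(ncol(x)))
  list(x = x, labels = labels)
}

test_that("confusion metrics follow the standard definitions", {
  m <- metrics_from_confusion(46, 46, 0, 0)
  expect_equal(m[["acc"]], 1); expect_equal(m[["f1"]], 1)
  expect_equal(metrics_from_confusion(0, 46, 0, 46)[["recall"]], 0)
  m <- metrics_from_confusion(30, 40, 6, 16)
  expect_equal(m[["acc"]], 70 / 92)
  expect_equal(m[["precision"]], 30 / 36)
  expect_equal(m[["recall"]], 30 / 46)
  p <- 30 / 36; r <- 30 / 46
  expect_equal(m[["f1"]], 2 * p * r / (p + r))
  ## undefined ratios surface as NA, never 0
  expect_true(is.na(metrics_from_confusion(0, 10, 0, 5)[["precision"]]))
  expect_true(is.na(metrics_from_confusion(0, 10, 0, 0)[["recall"]]))
})

test_that("the default hyperparameter grid enumerates 22 combinations", {
  g <- default_svm_grid()
  expect_equal(nrow(g), 22L)
  expect_equal(sum(g$kernel == "linear"), 4L)
  expect_equal(sum(g$kernel == "polynomial"), 2L)
  expect_equal(sum(g$kernel == "radial"), 16L)
  expect_setequal(unique(g$cost), c(1, 10, 100, 1000))
})

test_that("RFE ranking is a permutation and recovers informative features", {
  d <- gaussian_features(12, 2, 20, 4, seed = 31)
  rk <- rfe_rank(d$x, d$labels, seed = 1)
  expect_setequal(rk$ranking, colnames(d$x))
  expect_true(all(rk$weights >= 0))
  ## recovery over seeds: both informative features in the top 5
  hits <- vapply(1:10, function(s) {
    di <- gaussian_features(12, 2, 20, 4, seed = 300 + s)
    ri <- rfe_rank(di$x, di$labels, seed = s)
    all(c("F1", "F2") %in% ri$ranking[1:5])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("duplicate feature columns earn adjacent ranks, ties by index", {
  ## exactly duplicated noise next to strongly informative columns: the
  ## pair carries (equal) minimal weight throughout, so the copies leave in
  ## consecutive rounds, lower column index first
  d <- gaussian_features(10, 2, 1, 3, seed = 17)
  x <- cbind(d$x, DUP = d$x[, "F3"])
  rk <- rfe_rank(x, d$labels, seed = 2)
  pos <- sort(match(c("F3", "DUP"), rk$ranking))
  expect_equal(diff(pos), 1L)
  ## lower index eliminated first => ranked less important
  expect_gt(match("F3", rk$ranking), match("DUP", rk$ranking))
})

test_that("block elimination preserves the strongest features", {
  d <- gaussian_features(12, 2, 30, 3, seed = 77)
  rk <- rfe_rank(d$x, d$labels, seed = 3, elim_step = 5L)
  expect_setequal(rk$ranking, colnames(d$x))
  expect_true(all(c("F1", "F2") %in% rk$ranking[1:8]))
})

test_that("classification is deterministic given the seed", {
  d <- gaussian_features(10, 2, 6, 1.5, seed = 41)
  g <- default_svm_grid()[c(1, 3, 7), ]
  r1 <- svm_classify(d$x, d$labels, grid = g, cv_folds = 5,
                     n_repeats = 3, seed = 9)
  r2 <- svm_classify(d$x, d$labels, grid = g, cv_folds = 5,
                     n_repeats = 3, seed = 9)
  expect_identical(r1$aggregate, r2$aggregate)
  expect_identical(r1$per_repeat, r2$per_repeat)
})

test_that("well-separated Gaussians classify nearly perfectly", {
  d <- gaussian_features(46, 4, 8, 3, seed = 53)
  rep_ <- svm_classify(d$x, d$labels, cv_folds = 10, n_repeats = 3,
                       seed = 5)
  expect_gt(rep_$aggregate[["acc"]], 0.95)
  expect_gt(rep_$aggregate[["auc"]], 0.95)
  expect_true(all(rep_$per_repeat$acc >= 0 & rep_$per_repeat$acc <= 1))
})

test_that("identical features classify at chance on balanced labels", {
  set.seed(61)
  n <- 40L
  x <- matrix(rep(rnorm(n), 3), n)   # identical columns per subject
  x <- x + matrix(rnorm(3 * n, sd = 1e-8), n)
  labels <- rep(c(1L, 0L), each = n / 2L)
  rep_ <- svm_classify(x, labels, grid = default_svm_grid()[1, ,
                                                            drop = FALSE],
                       cv_folds = 5, n_repeats = 3, seed = 6)
  expect_lt(abs(rep_$aggregate[["acc"]] - 0.5), 3 * sqrt(0.25 / n) + 0.1)
})

test_that("the top-N sweep finds the informative feature count", {
  d <- gaussian_features(20, 3, 12, 4, seed = 71)
  rk <- rfe_rank(d$x, d$labels, seed = 7)
  sw <- topn_accuracy_sweep(d$x, d$labels, rk,
                            grid = default_svm_grid()[1, , drop = FALSE],
                            n_values = 1:8, cv_folds = 5, seed = 7)
  expect_equal(nrow(sw$sweep), 8L)
  expect_equal(length(sw$selected_features), sw$best_n)
  ## separable at N >= 3: accuracy saturates near 1
  expect_gte(max(sw$sweep$accuracy[sw$sweep$n >= 3]), 0.95)
  expect_error(topn_accuracy_sweep(d$x, d$labels, rk, n_max = 99),
               "exceeds")
})

test_that("label permutation stays inside the binomial null band", {
  d <- gaussian_features(23, 2, 10, 3, seed = 83)
  set.seed(83)
  perm <- sample(d$labels)
  rep_ <- svm_classify(d$x, perm, grid = default_svm_grid()[c(1, 10), ],
                       cv_folds = 10, n_repeats = 5, seed = 8)
  n <- length(perm)
  expect_lt(abs(rep_$aggregate[["acc"]] - 0.5), 3 * sqrt(0.25 / n))
})

test_that("in-fold selection guards against selection leakage under the null", {
  ## pure noise, many features: selecting on the full data then
  ## cross-validating is optimistic; the in-train selector is not
  set.seed(91)
  n <- 40L
  x <- matrix(rnorm(n * 60), n)
  colnames(x) <- paste0("F", 1:60)
  labels <- rep(c(1L, 0L), each = n / 2L)
  rep_ <- svm_classify(x, labels, grid = default_svm_grid()[1, ,
                                                            drop = FALSE],
                       cv_folds = 5, n_repeats = 4, seed = 10,
                       selector = mfdfc:::rfe_selector(5L))
  expect_lt(abs(rep_$aggregate[["acc"]] - 0.5), 3 * sqrt(0.25 / n))
})
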