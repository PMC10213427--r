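test_that("segment counts reproduce the window bookkeeping", {
  expect_equal(count_segments(142, 15, 5), 26L)
  expect_equal(count_segments(142, 20, 5), 25L)
  expect_equal(count_segments(142, 25, 5), 24L)
  expect_equal(count_segments(142, 30, 5), 23L)
  expect_equal(count_segments(10, 10, 5), 1L)
  expect_error(count_segments(10, 11, 5), "exceeds")
})

test_that("sliding-window correlation matches the brute-force oracle", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(40:142, 1)
    w <- sample(10:30, 1)
    st <- sample(1:7, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- sliding_window_corr(x, y, w, st)
    want <- swc_oracle(x, y, w, st)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(abs(got) <= 1 + 1e-12))
    ## symmetry in (x, y)
    expect_identical(got, sliding_window_corr(y, x, w, st))
  }
})

test_that("degenerate windows behave as documented", {
  x <- seq_len(30) + 0.5
  expect_equal(sliding_window_corr(x, x, 10, 5), rep(1, 5))
  ## whole-series window equals the plain Pearson correlation
  set.seed(3)
  y <- rnorm(30)
  expect_equal(sliding_window_corr(x, y, 30, 5), cor(x, y))
  ## zero-variance window -> warning, value 0
  z <- c(rep(1, 15), rnorm(15))
  expect_warning(r <- sliding_window_corr(z, y, 10, 5), "zero-variance")
  expect_equal(r[1], 0)
})

test_that("dFC feature matrices carry the Table-style column counts", {
  ## 10 + 5 selected ROIs -> 55 pair features per segment; at N = 142,
  ## step 5: 26/25/24/23 segments -> 1430/1375/1320/1265 columns
  co <- generate_cohort(cohort_spec(n_per_group = 2L, n_rois = 15L,
                                    n_timepoints = 142L, noise_sd = 0.5,
                                    seed = 4L))
  sel <- list("Slow-5" = 1:5, "Slow-4" = 6:15)
  for (spec_w in list(c(15, 1430), c(20, 1375), c(25, 1320), c(30, 1265))) {
    dm <- build_dfc_features(co, sel, "Combined",
                             config = list(width = spec_w[1], step = 5))
    expect_equal(ncol(dm$values), spec_w[2])
    expect_equal(nrow(dm$values), 4L)
  }
  dm <- build_dfc_features(co, sel, "Combined",
                           config = list(width = 15, step = 5))
  expect_true(all(dm$values >= -1 & dm$values <= 1))
  ## index map covers every column once, band-major then segment then pair
  expect_equal(dm$index_map$feature_id, colnames(dm$values))
  expect_equal(anyDuplicated(dm$index_map$feature_id), 0L)
  expect_equal(unique(dm$index_map$band), c("Slow-5", "Slow-4"))
  slow5 <- dm$index_map[dm$index_map$band == "Slow-5", ]
  expect_equal(nrow(slow5), choose(5, 2) * 26)
  expect_true(all(slow5$roi_a < slow5$roi_b))
})

test_that("single-band, two-ROI, one-segment input yields one feature", {
  co <- generate_cohort(cohort_spec(n_per_group = 2L, n_rois = 2L,
                                    n_timepoints = 40L, seed = 9L))
  dm <- build_dfc_features(co, list("Slow-4" = 1:2),
                           config = list(width = 40, step = 5))
  expect_equal(ncol(dm$values), 1L)
})

test_that("per-window values equal windowed correlations of filtered series", {
  co <- generate_cohort(cohort_spec(n_per_group = 2L, n_rois = 3L,
                                    n_timepoints = 80L, seed = 12L))
  dm <- build_dfc_features(co, list("Slow-4" = c(1L, 3L)),
                           config = list(width = 20, step = 5))
  lim <- n3l_band_limits(4)
  m <- co$series[[1]]
  f1 <- bandpass(m[1, ], lim[["f_low"]], lim[["f_high"]], 2)
  f3 <- bandpass(m[3, ], lim[["f_low"]], lim[["f_high"]], 2)
  want <- swc_oracle(f1, f3, 20L, 5L)
  expect_equal(as.numeric(dm$values[1, ]), want, tolerance = 1e-12)
})

test_that("mixed per-band window widths concatenate band-block-wise", {
  co <- generate_cohort(cohort_spec(n_per_group = 2L, n_rois = 15L,
                                    n_timepoints = 142L, seed = 5L))
  sel <- list("Slow-5" = 1:5, "Slow-4" = 6:15)
  mix <- mixed_window_features(co, sel,
                               configs = list("Slow-5" = list(width = 15,
                                                              step = 5),
                                              "Slow-4" = list(width = 20,
                                                              step = 5)))
  ## 26 segs x 10 pairs + 25 segs x 45 pairs = 260 + 1125 = 1385
  expect_equal(ncol(mix$values), 1385L)
  expect_equal(anyDuplicated(mix$index_map$feature_id), 0L)
  ## equal configs reduce to the plain builder
  same <- mixed_window_features(co, sel,
                                configs = list("Slow-5" = list(width = 20,
                                                               step = 5),
                                               "Slow-4" = list(width = 20,
                                                               step = 5)))
  plain <- build_dfc_features(co, sel, config = list(width = 20, step = 5))
  expect_equal(same$values, plain$values)
})

test_that("Conventional scheme filters with the conventional mask", {
  co <- generate_cohort(cohort_spec(n_per_group = 2L, n_rois = 4L,
                                    n_timepoints = 80L, seed = 6L))
  sel <- list("Slow-5" = 1:2, "Slow-4" = 3:4)
  dm <- build_dfc_features(co, sel, scheme = "Conventional",
                           config = list(width = 20, step = 5))
  m <- co$series[[1]]
  f1 <- bandpass(m[1, ], 0.01, 0.08, 2)
  f2 <- bandpass(m[2, ], 0.01, 0.08, 2)
  want <- swc_oracle(f1, f2, 20L, 5L)
  block <- dm$index_map$band == "Slow-5" & dm$index_map$roi_a == 1L
  expect_equal(as.numeric(dm$values[1, block]), want, tolerance = 1e-12)
})

test_that("pairwise counts partition the selected feature set", {
  co <- generate_cohort(cohort_spec(n_per_group = 2L, n_rois = 6L,
                                    n_timepoints = 100L, seed = 7L))
  sel <- list("Slow-4" = 1:4)
  dm <- build_dfc_features(co, sel, config = list(width = 20, step = 5))
  cnt0 <- pairwise_discriminative_counts(dm, character(0))
  expect_true(all(cnt0$count == 0))
  expect_equal(nrow(cnt0), choose(4, 2))
  chosen <- sample(dm$index_map$feature_id, 17)
  cnt <- pairwise_discriminative_counts(dm, chosen)
  expect_equal(sum(cnt$count), 17L)
})
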