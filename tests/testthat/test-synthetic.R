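test_that("cohort specs validate their fields with informative errors", {
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(n_rois = 1), "n_rois")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(falff_effects = list(list(roi = 99,
                                                     band = "Slow-4",
                                                     multiplier = 2)),
                           n_rois = 10), "falff_effects")
  expect_error(cohort_spec(falff_effects = list(list(roi = 2,
                                                     band = "Slow-4",
                                                     multiplier = 0)),
                           n_rois = 10), "multiplier")
  expect_error(cohort_spec(dfc_effects = list(list(roi_a = 1, roi_b = 1,
                                                   band = "Slow-4",
                                                   case_correlation = 0.5,
                                                   control_correlation = 0))),
               "roi_a")
  expect_error(cohort_spec(falff_effects = list(list(roi = 2,
                                                     band = "NotABand",
                                                     multiplier = 2)),
                           n_rois = 10), "unresolvable")
})

test_that("generation is bit-identical given the seed and has spec shape", {
  sp <- cohort_spec(n_per_group = 3L, n_rois = 5L, n_timepoints = 60L,
                    seed = 7L)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1$series, c2$series)
  expect_identical(c1$labels, c2$labels)
  expect_equal(length(c1$series), 6L)
  expect_true(all(vapply(c1$series, function(m)
    identical(dim(m), c(5L, 60L)), logical(1))))
  expect_equal(sum(c1$labels == 1L), 3L)    # balanced, cases first
  expect_equal(c1$labels, rep(c(1L, 0L), each = 3L))
  ## a different seed changes the data
  c3 <- generate_cohort(cohort_spec(n_per_group = 3L, n_rois = 5L,
                                    n_timepoints = 60L, seed = 8L))
  expect_false(identical(c1$series, c3$series))
})

test_that("paper-scale dimensions come out as specified", {
  sp <- cohort_spec(seed = 1L)   # defaults: 46+46, 90 ROIs, 142 tp, TR 2
  expect_equal(sp$n_per_group, 46L)
  expect_equal(sp$n_rois, 90L)
  expect_equal(sp$n_timepoints, 142L)
  expect_equal(sp$tr_seconds, 2)
})

test_that("injected fALFF effects realise with the correct sign over seeds", {
  diffs <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(
      n_per_group = 6L, n_rois = 6L, n_timepoints = 100L,
      falff_effects = list(list(roi = 5L, band = "Slow-5",
                                multiplier = 2)),
      noise_sd = 0.3, seed = 1000L + s))
    fm <- build_falff_features(co, "Slow-5")
    mean(fm$values[co$labels == 1L, "ROI5@Slow-5"]) -
      mean(fm$values[co$labels == 0L, "ROI5@Slow-5"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("injected pair correlations realise in band-passed series", {
  rho_hat <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_spec(
      n_per_group = 4L, n_rois = 4L, n_timepoints = 142L,
      dfc_effects = list(list(roi_a = 1L, roi_b = 2L, band = "Slow-4",
                              case_correlation = 0.8,
                              control_correlation = 0)),
      noise_sd = 0.1, seed = 2000L + s))
    lim <- n3l_band_limits(4)
    per_subj <- vapply(seq_along(co$series), function(i) {
      m <- co$series[[i]]
      cor(bandpass(m[1, ], lim[["f_low"]], lim[["f_high"]], 2),
          bandpass(m[2, ], lim[["f_low"]], lim[["f_high"]], 2))
    }, numeric(1))
    mean(per_subj[co$labels == 1L]) - mean(per_subj[co$labels == 0L])
  }, numeric(1))
  ## cases should be substantially more correlated than controls
  expect_gt(mean(rho_hat), 0.3)
})

test_that("the truth table mirrors the injected effects and resolves", {
  co <- tiny_cohort()
  tt <- effect_truth_table(co)
  expect_equal(nrow(tt), 2L)
  expect_setequal(tt$type, c("falff", "dfc"))
  expect_equal(tt$expected_direction, rep("case>control", 2))
  ## ids resolve in the corresponding index maps
  fm <- build_falff_features(co, "Combined")
  expect_true(tt$feature_id[tt$type == "falff"] %in% fm$index_map$feature_id)
  dm <- build_dfc_features(co, list("Slow-5" = c(4L, 5L)),
                           config = list(width = 20, step = 5))
  pair_ids <- unique(paste0(dm$index_map$band, ":ROI", dm$index_map$roi_a,
                            "-ROI", dm$index_map$roi_b))
  expect_true(tt$feature_id[tt$type == "dfc"] %in% pair_ids)
  ## no effects -> empty table
  empty <- generate_cohort(cohort_spec(n_per_group = 2L, n_rois = 3L,
                                       n_timepoints = 40L, seed = 3L))
  expect_equal(nrow(effect_truth_table(empty)), 0L)
})

test_that("voxel expansion round-trips through roi_average", {
  co <- tiny_cohort()
  vx <- cohort_to_voxels(co, voxels_per_roi = 3L, voxel_noise_sd = 0)
  back <- roi_average(vx$voxel_series[[1]], vx$roi_labels)
  expect_equal(unname(back), co$series[[1]], tolerance = 1e-12)
})

test_that("cohorts round-trip through the TSV writer", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "labels.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_cohort(dir)
  expect_equal(back$labels, co$labels)
  expect_equal(back$series, co$series, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back$spec$falff_effects[[1]]$roi,
               co$spec$falff_effects[[1]]$roi)
})
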