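#' Fit the multi-frequency dynamic-connectivity classifier
#'
#' End-to-end two-stage fit on a case/control cohort of regional BOLD time
#' series. Stage one computes band-wise fALFF (Slow-5 and Slow-4 of the
#' natural-logarithm band ladder) per region, ranks regions by recursive
#' feature elimination and selects the discriminative set from the top-N
#' accuracy sweep. Stage two band-passes the selected regions' series,
#' extracts sliding-window Pearson correlations at each requested window
#' width, re-selects and classifies with a grid-searched SVM under repeated
#' stratified cross-validation — for the Combined (Slow-5 + Slow-4) scheme
#' and, for comparison, the Conventional 0.01–0.08 Hz scheme.
#'
#' @param x A `synthetic_cohort` (see [generate_cohort()]) or a list of
#'   per-subject ROI x time matrices.
#' @param labels 0/1 group indicator, 1 = case (taken from the cohort when
#'   `x` is one).
#' @param schemes Band schemes evaluated in the connectivity stage.
#' @param widths Sliding-window widths in TRs.
#' @param step Window step in TRs.
#' @param tr_seconds Repetition time in seconds.
#' @param padded_length Zero-padded transform length for the band-pass
#'   filters of the connectivity stage.
#' @param falff_padded_length Transform length for the fALFF spectra
#'   (default: the unpadded series length; see [alff()]).
#' @param grid SVM hyperparameter grid ([default_svm_grid()], 22 rows).
#' @param cv_folds Cross-validation folds.
#' @param n_repeats CV repeats for the reported classification metrics.
#' @param sweep_repeats CV repeats inside the top-N sweeps.
#' @param falff_sweep_n,dfc_sweep_n Optional N values for the two sweeps
#'   (defaults: every N for fALFF; 2,4,...,60 for the much wider dFC
#'   matrix).
#' @param falff_rfe_step,dfc_rfe_step Features eliminated per RFE round in
#'   each stage.
#' @param select_in_train Re-select dFC features inside each training fold
#'   (leakage-free, default) rather than once on the full cohort.
#' @param mixed_configs Optional mixed-width combinations, passed to
#'   [run_dfc_stage()].
#' @param seed Integer seed governing every randomised step.
#' @return An object of class `mfdfc`; see [summary.mfdfc()],
#'   [coef.mfdfc()], [plot.mfdfc()], [predict.mfdfc()].
#' @export
#' @examples
#' \donttest{
#' sp <- cohort_spec(n_per_group = 10, n_rois = 8, n_timepoints = 80,
#'                   falff_effects = list(list(roi = 2, band = "Slow-4",
#'                                             multiplier = 2)),
#'                   noise_sd = 0.4, seed = 3)
#' fit <- mfdfc(generate_cohort(sp), widths = 20, schemes = "Combined",
#'              n_repeats = 2)
#' summary(fit)
#' }
mfdfc <- function(x, labels = NULL,
                  schemes = c("Combined", "Conventional"),
                  widths = c(15L, 20L, 25L, 30L), step = 5L,
                  tr_seconds = 2, padded_length = 4096L,
                  falff_padded_length = NULL,
                  grid = default_svm_grid(), cv_folds = 10L,
                  n_repeats = 10L, sweep_repeats = 1L,
                  falff_sweep_n = NULL, dfc_sweep_n = NULL,
                  falff_rfe_step = 1L, dfc_rfe_step = 5L,
                  select_in_train = TRUE, mixed_configs = NULL,
                  seed = 1L) {
  cl <- match.call()
  if (inherits(x, "synthetic_cohort")) {
    labels <- x$labels
    tr_seconds <- x$spec$tr_seconds
  }
  stopifnot(!is.null(labels))
  timings <- c()
  t0 <- Sys.time()
  falff_stage <- run_falff_stage(
    x, labels, scheme = "Combined", tr_seconds = tr_seconds,
    padded_length = falff_padded_length, grid = grid, cv_folds = cv_folds,
    sweep_n_values = falff_sweep_n, sweep_repeats = sweep_repeats,
    rfe_step = falff_rfe_step, seed = seed)
  timings["falff_stage"] <- as.numeric(Sys.time() - t0, units = "secs")
  t0 <- Sys.time()
  dfc_stage <- run_dfc_stage(
    x, falff_stage$selected_rois, labels, schemes = schemes,
    widths = widths, step = step, tr_seconds = tr_seconds,
    padded_length = padded_length, grid = grid, cv_folds = cv_folds,
    n_repeats = n_repeats, sweep_n_values = dfc_sweep_n,
    sweep_repeats = sweep_repeats, rfe_step = dfc_rfe_step,
    select_in_train = select_in_train, mixed_configs = mixed_configs,
    seed = seed)
  timings["dfc_stage"] <- as.numeric(Sys.time() - t0, units = "secs")

  reports <- dfc_stage$reports
  best_i <- which.max(reports$acc)
  best <- dfc_stage$details[[best_i]]
  ## final model refit on all subjects: the best combination's selected
  ## features with the hyperparameters its CV chose most often
  pr <- best$report$per_repeat
  key <- paste(pr$kernel, pr$cost, pr$degree, pr$gamma)
  mode_row <- pr[match(names(which.max(table(key))), key), , drop = FALSE]
  combo <- data.frame(kernel = mode_row$kernel, cost = mode_row$cost,
                      degree = mode_row$degree, gamma = mode_row$gamma)
  feats <- best$dfc$values[, best$sweep$selected_features, drop = FALSE]
  sc <- scale_fit(feats)
  final <- svm_fit_predict(scale_apply(feats, sc), labels,
                           scale_apply(feats, sc), combo)$fit

  manifest <- list(package_version = as.character(utils::packageVersion("mfdfc")),
                   seed = seed, tr_seconds = tr_seconds,
                   padded_length = padded_length, schemes = schemes,
                   widths = widths, step = step, cv_folds = cv_folds,
                   n_repeats = n_repeats,
                   n_subjects = length(labels),
                   n_rois = nrow(if (is.list(x) && !inherits(x, "synthetic_cohort"))
                     x[[1]] else x$series[[1]]),
                   timings_sec = as.list(round(timings, 2)))
  structure(list(falff_stage = falff_stage, dfc_stage = dfc_stage,
                 reports = reports, best_combination = reports$combination[best_i],
                 final_model = list(svm = final, scaler = sc, combo = combo,
                                    features = best$sweep$selected_features,
                                    selected_rois = falff_stage$selected_rois,
                                    scheme = reports$scheme[best_i],
                                    config = best$dfc$config,
                                    tr_seconds = tr_seconds,
                                    padded_length = padded_length),
                 labels = as.integer(labels), manifest = manifest,
                 call = cl),
            class = "mfdfc")
}

#' @export
print.mfdfc <- function(x, ...) {
  cat("Multi-frequency dFC classifier\n")
  cat("  subjects:", x$manifest$n_subjects,
      " regions:", x$manifest$n_rois,
      " seed:", x$manifest$seed, "\n")
  rois <- x$falff_stage$selected_rois
  cat("  fALFF-selected regions:",
      paste(sprintf("%s: %d", names(rois),
                    vapply(rois, length, integer(1))), collapse = ", "),
      "\n")
  cat("  best combination:", x$best_combination,
      sprintf("(ACC %.3f, AUC %.3f)\n",
              x$reports$acc[x$reports$combination == x$best_combination],
              x$reports$auc[x$reports$combination == x$best_combination]))
  invisible(x)
}

#' Summarise a fitted multi-frequency dFC classifier
#'
#' @param object An `mfdfc` fit.
#' @param ... Unused.
#' @return The classification report table, invisibly.
#' @export
summary.mfdfc <- function(object, ...) {
  print(object)
  cat("\nClassification by scheme and window width (means over",
      object$manifest$n_repeats, "repeats):\n")
  tab <- object$reports
  tab[, c("auc", "acc", "f1", "precision", "recall")] <-
    round(tab[, c("auc", "acc", "f1", "precision", "recall")], 4)
  print(tab, row.names = FALSE)
  cat("\nSelected regions per band (stage one):\n")
  for (bn in names(object$falff_stage$selected_rois)) {
    cat("  ", bn, ": ",
        paste(object$falff_stage$selected_rois[[bn]], collapse = ", "),
        "\n", sep = "")
  }
  invisible(object$reports)
}

#' Ranked feature weights of a fitted classifier
#'
#' Returns the recursive-elimination weights (absolute ranking-estimator
#' coefficient at elimination) of the selected features, most important
#' first — the per-feature importance table.
#'
#' @param object An `mfdfc` fit.
#' @param stage `"falff"` (stage-one region features) or `"dfc"` (the best
#'   combination's connectivity features).
#' @param ... Unused.
#' @return Data.frame `feature_id`, `weight`.
#' @export
coef.mfdfc <- function(object, stage = c("dfc", "falff"), ...) {
  stage <- match.arg(stage)
  if (stage == "falff") {
    rk <- object$falff_stage$ranking
    sel <- object$falff_stage$selected_features
  } else {
    det <- object$dfc_stage$details[[object$best_combination]]
    rk <- det$ranking
    sel <- det$sweep$selected_features
  }
  keep <- rk$ranking %in% sel
  data.frame(feature_id = rk$ranking[keep], weight = rk$weights[keep],
             stringsAsFactors = FALSE)
}

#' Plot fitted-model diagnostics
#'
#' `which = "sweep"` draws the stage-one top-N accuracy curve;
#' `"reports"` the classification accuracy per scheme across window widths;
#' `"counts"` a heatmap of how many temporal segments per region pair
#' carried a selected connectivity feature (best combination).
#'
#' @param x An `mfdfc` fit.
#' @param which One of "sweep", "reports", "counts".
#' @param ... Passed to the underlying base-graphics call.
#' @return `x`, invisibly.
#' @export
plot.mfdfc <- function(x, which = c("sweep", "reports", "counts"), ...) {
  which <- match.arg(which)
  if (which == "sweep") {
    sw <- x$falff_stage$sweep$sweep
    plot(sw$n, sw$accuracy, type = "b", pch = 16,
         xlab = "top-N ranked fALFF features",
         ylab = "cross-validated accuracy",
         main = "Stage one: feature-count sweep", ...)
    abline(v = x$falff_stage$sweep$best_n, lty = 2)
  } else if (which == "reports") {
    tab <- x$reports[!is.na(x$reports$width), ]
    schemes <- unique(tab$scheme)
    plot(range(tab$width), range(tab$acc), type = "n",
         xlab = "window width (TRs)", ylab = "mean CV accuracy",
         main = "Stage two: scheme x window width", ...)
    for (i in seq_along(schemes)) {
      sub <- tab[tab$scheme == schemes[i], ]
      lines(sub$width, sub$acc, type = "b", pch = i, lty = i)
    }
    legend("bottomleft", legend = schemes, pch = seq_along(schemes),
           lty = seq_along(schemes), bty = "n")
  } else {
    det <- x$dfc_stage$details[[x$best_combination]]
    cnt <- det$counts
    rois <- sort(unique(c(cnt$roi_a, cnt$roi_b)))
    m <- matrix(0, length(rois), length(rois),
                dimnames = list(rois, rois))
    for (i in seq_len(nrow(cnt))) {
      a <- match(cnt$roi_a[i], rois); b <- match(cnt$roi_b[i], rois)
      m[a, b] <- m[a, b] + cnt$count[i]
      m[b, a] <- m[a, b]
    }
    image(seq_along(rois), seq_along(rois), m, axes = FALSE,
          xlab = "ROI", ylab = "ROI",
          main = "Selected segments per region pair", ...)
    axis(1, seq_along(rois), rois); axis(2, seq_along(rois), rois)
  }
  invisible(x)
}

#' Predict group membership for new subjects
#'
#' Rebuilds the fitted model's connectivity features (same selected
#' regions, band masks and window configuration) for new subjects and
#' applies the final SVM refit on the training cohort.
#'
#' @param object An `mfdfc` fit.
#' @param newdata A `synthetic_cohort` or list of ROI x time matrices with
#'   the same region count and series length as the training data.
#' @param type `"class"` for 0/1 labels, `"score"` for the continuous
#'   decision value (higher = more case-like).
#' @param ... Unused.
#' @return Integer labels or numeric scores, one per subject.
#' @export
predict.mfdfc <- function(object, newdata, type = c("class", "score"),
                          ...) {
  type <- match.arg(type)
  fm <- object$final_model
  dm <- build_dfc_features(newdata, fm$selected_rois, scheme = fm$scheme,
                           config = fm$config,
                           tr_seconds = fm$tr_seconds,
                           padded_length = fm$padded_length)
  xx <- scale_apply(dm$values[, fm$features, drop = FALSE], fm$scaler)
  pr <- stats::predict(fm$svm, xx, decision.values = TRUE)
  if (type == "class") return(as.integer(as.character(pr)))
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (identical(first, "1")) as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
}

#' Write the run manifest of a fit as JSON
#'
#' The manifest records the configuration, seed, package version, data
#' dimensions and per-stage wall-clock — enough to re-run a synthetic-mode
#' fit bit-identically.
#'
#' @param object An `mfdfc` fit.
#' @param path Output path.
#' @export
write_manifest <- function(object, path) {
  stopifnot(inherits(object, "mfdfc"))
  jsonlite::write_json(object$manifest, path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
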