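#' First stage: discriminative regions from band-wise fALFF
#'
#' Builds the subjects x (ROI, band) fALFF matrix for a scheme, ranks the
#' columns by recursive feature elimination, sweeps the top-N accuracy
#' curve, and returns the selected feature set (the "abnormal" regions) —
#' per band for the Combined scheme. The ranking and sweep are computed on
#' the full cohort, which is how exploratory selection curves are drawn;
#' the downstream classification stage re-selects inside training folds
#' unless asked not to.
#'
#' @param cohort A `synthetic_cohort`, or a list of ROI x time matrices.
#' @param labels 0/1 labels (ignored when `cohort` carries its own).
#' @param scheme Scheme label or [band_scheme()].
#' @param tr_seconds Repetition time in seconds.
#' @param padded_length Transform length for the fALFF spectra (default:
#'   the unpadded series length; see [alff()]).
#' @param grid,cv_folds Sweep classifier settings.
#' @param sweep_n_values N values evaluated in the sweep (default: all).
#' @param sweep_repeats CV repeats per swept N.
#' @param rfe_step Features eliminated per RFE round.
#' @param seed Integer seed.
#' @return List of class `falff_stage`: `falff` (the feature matrix),
#'   `ranking`, `sweep` (a `topn_sweep`), `selected_features`,
#'   `selected_rois` (named list band -> ROI indices).
#' @export
run_falff_stage <- function(cohort, labels = NULL, scheme = "Combined",
                            tr_seconds = 2, padded_length = NULL,
                            grid = default_svm_grid(), cv_folds = 10L,
                            sweep_n_values = NULL, sweep_repeats = 1L,
                            rfe_step = 1L, seed = 1L) {
  if (inherits(cohort, "synthetic_cohort")) {
    labels <- cohort$labels
    tr_seconds <- cohort$spec$tr_seconds
  }
  stopifnot(!is.null(labels))
  fm <- build_falff_features(cohort, scheme, tr_seconds, padded_length)
  rk <- rfe_rank(fm$values, labels, cv_folds = cv_folds, seed = seed,
                 elim_step = rfe_step)
  sw <- topn_accuracy_sweep(fm$values, labels, rk, grid = grid,
                            n_values = sweep_n_values, cv_folds = cv_folds,
                            n_repeats = sweep_repeats, seed = seed)
  sel <- sw$selected_features
  im <- fm$index_map[match(sel, fm$index_map$feature_id), ]
  selected_rois <- split(im$roi_index, im$band)
  selected_rois <- lapply(selected_rois, function(v) sort(unique(v)))
  structure(list(falff = fm, ranking = rk, sweep = sw,
                 selected_features = sel, selected_rois = selected_rois,
                 scheme = fm$scheme, seed = seed),
            class = "falff_stage")
}

## Halving-RFE selector factory: inside a training fold, recursively
## eliminates the lowest-|weight| half of features under the linear SVR
## estimator until n_select remain. Returns column indices.
rfe_selector <- function(n_select) {
  force(n_select)
  function(x, y) {
    sc <- scale_fit(x)
    xs <- scale_apply(x, sc)
    remaining <- seq_len(ncol(x))
    yn <- as.numeric(y)
    while (length(remaining) > n_select) {
      w <- abs(svr_weights(xs[, remaining, drop = FALSE], yn))
      k <- min(length(remaining) - n_select,
               max(1L, floor(length(remaining) / 2)))
      drop_local <- order(w, seq_along(w))[seq_len(k)]
      remaining <- remaining[-drop_local]
    }
    remaining
  }
}

#' Second stage: dynamic-connectivity classification per scheme and width
#'
#' For each requested (scheme, window width) combination: builds the
#' sliding-window dFC feature matrix among the selected regions, ranks it
#' by recursive elimination, sweeps the top-N curve to fix the selected
#' feature count, and reports repeated cross-validated classification. With
#' `select_in_train = TRUE` (default) the features entering each CV fold's
#' model are re-selected by a halving RFE on that fold's training subjects
#' only, so held-out metrics are free of selection leakage; `FALSE`
#' classifies the full-cohort-selected columns directly, which mirrors the
#' common rank-once workflow but is optimistic.
#'
#' @inheritParams run_falff_stage
#' @param selected_rois Named list band -> ROI indices (e.g. from
#'   [run_falff_stage()] on the Combined scheme).
#' @param schemes Character vector of scheme labels to evaluate.
#' @param widths Window widths in TRs.
#' @param step Window step in TRs.
#' @param n_repeats CV repeats for the reported classification.
#' @param rfe_step Elimination block size for the full-matrix ranking.
#' @param select_in_train Re-select features inside training folds (see
#'   Details).
#' @param mixed_configs Optional named list of per-band window configs for
#'   additional mixed-width rows (each element itself a named list
#'   band -> `list(width, step)`).
#' @return List of class `dfc_stage`: `reports` (one row per combination:
#'   scheme, width, auc, acc, f1, precision, recall), `details` (per
#'   combination: the `dfc_matrix`, ranking, sweep, report, pair counts).
#' @export
run_dfc_stage <- function(cohort, selected_rois, labels = NULL,
                          schemes = c("Combined", "Conventional"),
                          widths = c(15L, 20L, 25L, 30L), step = 5L,
                          tr_seconds = 2, padded_length = 4096L,
                          grid = default_svm_grid(), cv_folds = 10L,
                          n_repeats = 10L, sweep_n_values = NULL,
                          sweep_repeats = 1L, rfe_step = 5L,
                          select_in_train = TRUE, mixed_configs = NULL,
                          seed = 1L) {
  if (inherits(cohort, "synthetic_cohort")) {
    labels <- cohort$labels
    tr_seconds <- cohort$spec$tr_seconds
  }
  stopifnot(!is.null(labels), length(selected_rois) >= 1L)
  combos <- data.frame(scheme = rep(schemes, each = length(widths)),
                       width = rep(widths, times = length(schemes)),
                       stringsAsFactors = FALSE)
  configs <- lapply(seq_len(nrow(combos)), function(i)
    list(width = combos$width[i], step = step))
  labels_combo <- sprintf("%s@%dTR", combos$scheme, combos$width)
  if (!is.null(mixed_configs)) {
    for (nm in names(mixed_configs)) {
      combos <- rbind(combos, data.frame(scheme = "Combined", width = NA))
      configs[[length(configs) + 1L]] <- mixed_configs[[nm]]
      labels_combo <- c(labels_combo, nm)
    }
  }
  details <- vector("list", nrow(combos))
  names(details) <- labels_combo
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    dm <- build_dfc_features(cohort, selected_rois,
                             scheme = combos$scheme[i],
                             config = configs[[i]],
                             tr_seconds = tr_seconds,
                             padded_length = padded_length)
    rk <- rfe_rank(dm$values, labels, cv_folds = cv_folds, seed = seed,
                   elim_step = rfe_step)
    nv <- sweep_n_values
    if (is.null(nv)) nv <- unique(pmin(ncol(dm$values),
                                       seq(2L, 60L, by = 2L)))
    sw <- topn_accuracy_sweep(dm$values, labels, rk, grid = grid,
                              n_values = nv, cv_folds = cv_folds,
                              n_repeats = sweep_repeats, seed = seed)
    if (select_in_train) {
      rep_ <- svm_classify(dm$values, labels, grid = grid,
                           cv_folds = cv_folds, n_repeats = n_repeats,
                           seed = seed,
                           selector = rfe_selector(sw$best_n))
    } else {
      rep_ <- svm_classify(dm$values[, sw$selected_features, drop = FALSE],
                           labels, grid = grid, cv_folds = cv_folds,
                           n_repeats = n_repeats, seed = seed)
    }
    counts <- pairwise_discriminative_counts(dm, sw$selected_features)
    details[[i]] <- list(dfc = dm, ranking = rk, sweep = sw,
                         report = rep_, counts = counts)
    rows[[i]] <- data.frame(combination = labels_combo[i],
                            scheme = combos$scheme[i],
                            width = combos$width[i],
                            auc = rep_$aggregate[["auc"]],
                            acc = rep_$aggregate[["acc"]],
                            f1 = rep_$aggregate[["f1"]],
                            precision = rep_$aggregate[["precision"]],
                            recall = rep_$aggregate[["recall"]],
                            n_features = sw$best_n,
                            stringsAsFactors = FALSE)
  }
  reports <- do.call(rbind, rows)
  rownames(reports) <- NULL
  structure(list(reports = reports, details = details, seed = seed),
            class = "dfc_stage")
}

#' Read preprocessed 4-D BOLD volumes into ROI time series
#'
#' Loads each subject's 4-D NIfTI volume, drops the first `drop_initial`
#' volumes (signal-equilibration scans; every other preprocessing step is
#' assumed done upstream), and averages voxels within each atlas label into
#' one regional series. Requires the RNifti package.
#'
#' @param bold_paths Character vector of 4-D NIfTI paths (one per subject).
#' @param atlas_path 3-D integer-labelled atlas NIfTI on the same grid
#'   (0 = background).
#' @param drop_initial Leading volumes to discard (default 10).
#' @return Named list of ROI x time matrices (rows ordered by ascending
#'   atlas label).
#' @export
read_bold_nifti <- function(bold_paths, atlas_path, drop_initial = 10L) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required to read NIfTI volumes",
         call. = FALSE)
  }
  atlas <- as.integer(round(as.array(RNifti::readNifti(atlas_path))))
  out <- lapply(bold_paths, function(p) {
    img <- as.array(RNifti::readNifti(p))
    if (length(dim(img)) != 4L) {
      stop("expected a 4-D volume: ", p, call. = FALSE)
    }
    nvox <- prod(dim(img)[1:3])
    if (nvox != length(atlas)) {
      stop("atlas grid (", length(atlas), " voxels) does not match ", p,
           " (", nvox, " voxels)", call. = FALSE)
    }
    nt <- dim(img)[4]
    if (drop_initial >= nt) {
      stop("drop_initial (", drop_initial, ") >= volume count (", nt, ")",
           call. = FALSE)
    }
    vox <- matrix(img, nrow = nvox, ncol = nt)
    roi_average(vox, atlas)[, (drop_initial + 1L):nt, drop = FALSE]
  })
  names(out) <- sub("\\.nii(\\.gz)?$", "", basename(bold_paths))
  out
}
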