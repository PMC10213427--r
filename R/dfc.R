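#' Number of temporal segments for a sliding window
#'
#' Windows start at sample 1 and advance by `step`; trailing samples not
#' covered by a full window are dropped. For 142 time points with a 5-TR
#' step this gives 26, 25, 24 and 23 segments at widths 15, 20, 25, 30.
#'
#' @param n_timepoints Series length in TRs.
#' @param width Window width in TRs.
#' @param step Step length in TRs (default 5).
#' @return Integer segment count.
#' @export
count_segments <- function(n_timepoints, width, step = 5L) {
  stopifnot(width >= 2, step >= 1)
  if (width > n_timepoints) {
    stop("window width (", width, ") exceeds series length (", n_timepoints,
         ")", call. = FALSE)
  }
  as.integer(floor((n_timepoints - width) / step) + 1L)
}

#' Sliding-window Pearson correlation of two series
#'
#' Pearson correlation of `x[t..t+w-1]` and `y[t..t+w-1]` for window starts
#' `t = 1, 1+step, 1+2*step, ...`. A window in which either series has zero
#' variance has no defined correlation; it is recorded as 0 with a warning.
#'
#' @param x,y Numeric series of equal length.
#' @param width Window width in TRs.
#' @param step Step length in TRs.
#' @return Numeric vector of length `count_segments(length(x), width, step)`.
#' @export
sliding_window_corr <- function(x, y, width, step = 5L) {
  stopifnot(length(x) == length(y))
  n_seg <- count_segments(length(x), width, step)
  starts <- 1L + (seq_len(n_seg) - 1L) * step
  out <- vapply(starts, function(t0) {
    xs <- x[t0:(t0 + width - 1L)]
    ys <- y[t0:(t0 + width - 1L)]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
  if (anyNA(out)) {
    warning("zero-variance window(s): undefined correlation recorded as 0",
            call. = FALSE)
    out[is.na(out)] <- 0
  }
  out
}

## Window config: list(width=, step=) per band name, recycled from scalars.
normalise_window_config <- function(config, band_names) {
  if (is.numeric(config)) config <- list(width = config[[1]],
                                         step = if (length(config) > 1L)
                                           config[[2]] else 5L)
  if (!is.null(config$width)) {
    config <- stats::setNames(rep(list(config), length(band_names)),
                              band_names)
  }
  stopifnot(all(band_names %in% names(config)))
  config[band_names]
}

#' Sliding-window dFC feature matrix among selected ROIs
#'
#' For each band of the scheme: band-passes the ROI series of the ROIs
#' selected in that band (for the Conventional scheme the per-band ROI lists
#' are applied to the Conventional-band-passed series), computes the
#' sliding-window correlation for every unordered ROI pair, and concatenates
#' features band-major, then by segment, then by upper-triangle pair
#' (row-major). With 10 ROIs in Slow-4 and 5 in Slow-5 there are
#' 55 pair features per segment; at width 15 and step 5 on 142 time points
#' that is 26 segments and 1430 columns.
#'
#' Each band may carry its own window configuration (`config` as a named
#' list of `list(width, step)`), which is how mixed-window feature sets are
#' built; a single `list(width, step)` is recycled to all bands.
#'
#' @param series List of subject ROI x time matrices, or a
#'   `synthetic_cohort`.
#' @param selected_rois Named list: band name -> integer vector of ROI
#'   indices selected in that band.
#' @param scheme A [band_scheme()] or label; determines the band-pass mask
#'   ("Conventional" filters with the 0.01-0.08 Hz mask regardless of which
#'   band a ROI list came from).
#' @param config Window configuration (see Details).
#' @param tr_seconds,padded_length Spectral parameters.
#' @return Object of class `dfc_matrix`: `values` (subjects x features),
#'   `index_map` (`feature_id`, `band`, `segment`, `roi_a`, `roi_b`),
#'   `config`.
#' @export
build_dfc_features <- function(series, selected_rois, scheme = "Combined",
                               config = list(width = 20L, step = 5L),
                               tr_seconds = 2, padded_length = 4096L) {
  if (inherits(series, "synthetic_cohort")) {
    tr_seconds <- series$spec$tr_seconds
    series <- series$series
  }
  if (is.character(scheme)) scheme <- band_scheme(scheme)
  stopifnot(length(selected_rois) >= 1L,
            all(vapply(selected_rois, length, integer(1)) >= 1L))
  band_names <- names(selected_rois)
  if (is.null(band_names)) stop("'selected_rois' must be a named list",
                                call. = FALSE)
  config <- normalise_window_config(config, band_names)
  n_time <- ncol(series[[1]])
  n_rois <- nrow(series[[1]])
  conventional <- identical(scheme$label, "Conventional")

  n_per_band <- vapply(selected_rois, length, integer(1))
  if (any(n_per_band < 2L)) {
    drop_bands <- band_names[n_per_band < 2L]
    if (length(drop_bands) == length(band_names)) {
      stop("no band has >= 2 selected ROIs: no pairs to correlate",
           call. = FALSE)
    }
    warning("band(s) with a single selected ROI contribute no pair ",
            "features and are skipped: ",
            paste(drop_bands, collapse = ", "), call. = FALSE)
    band_names <- band_names[n_per_band >= 2L]
    selected_rois <- selected_rois[band_names]
    config <- config[band_names]
  }
  blocks <- lapply(band_names, function(bn) {
    rois <- sort(as.integer(selected_rois[[bn]]))
    if (any(rois < 1L | rois > n_rois)) {
      stop("ROI index out of range in band ", bn, call. = FALSE)
    }
    mask <- if (conventional) resolve_band("Conventional") else
      resolve_band(bn)
    w <- config[[bn]]$width
    st <- if (is.null(config[[bn]]$step)) 5L else config[[bn]]$step
    n_seg <- count_segments(n_time, w, st)
    pairs <- which(upper.tri(diag(length(rois))), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    idx <- do.call(rbind, lapply(seq_len(n_seg), function(s) {
      data.frame(band = bn, segment = s,
                 roi_a = rois[pairs[, 1]], roi_b = rois[pairs[, 2]],
                 stringsAsFactors = FALSE)
    }))
    raw <- vapply(series, function(m) {
      filt <- t(apply(m[rois, , drop = FALSE], 1, bandpass,
                      f_low = mask[["f_low"]], f_high = mask[["f_high"]],
                      tr_seconds = tr_seconds,
                      padded_length = padded_length))
      swc <- vapply(seq_len(nrow(pairs)), function(p) {
        sliding_window_corr(filt[pairs[p, 1], ], filt[pairs[p, 2], ], w, st)
      }, numeric(n_seg))
      ## swc is segments x pairs; flatten so pairs vary fastest per segment
      as.numeric(t(swc))
    }, numeric(n_seg * nrow(pairs)))
    vals <- if (is.matrix(raw)) t(raw) else matrix(raw, ncol = 1L)
    list(values = vals, index_map = idx,
         config = list(width = w, step = st))
  })
  values <- do.call(cbind, lapply(blocks, `[[`, "values"))
  index_map <- do.call(rbind, lapply(blocks, `[[`, "index_map"))
  index_map$feature_id <- paste0(index_map$band, ":seg", index_map$segment,
                                 ":ROI", index_map$roi_a, "-ROI",
                                 index_map$roi_b)
  index_map <- index_map[, c("feature_id", "band", "segment",
                             "roi_a", "roi_b")]
  colnames(values) <- index_map$feature_id
  structure(list(values = values, index_map = index_map,
                 config = stats::setNames(lapply(blocks, `[[`, "config"),
                                          band_names)),
            class = "dfc_matrix")
}

#' Mixed-window dFC features: one window width per band
#'
#' Convenience wrapper over [build_dfc_features()] for feature sets that use
#' a different sliding-window width in each band (for example Slow-5 at
#' 15 TRs with Slow-4 at 20 TRs); per-band segment counts may differ and
#' the feature blocks are concatenated band-wise.
#'
#' @inheritParams build_dfc_features
#' @param configs Named list: band name -> `list(width, step)`.
#' @return A `dfc_matrix`.
#' @export
mixed_window_features <- function(series, selected_rois, configs,
                                  scheme = "Combined", tr_seconds = 2,
                                  padded_length = 4096L) {
  build_dfc_features(series, selected_rois, scheme = scheme,
                     config = configs, tr_seconds = tr_seconds,
                     padded_length = padded_length)
}

#' Per-pair counts of discriminative temporal segments
#'
#' Given the dFC features retained by feature selection, counts for every
#' (ROI pair, band) how many temporal segments contributed a selected
#' sliding-window correlation feature — the summary usually displayed as a
#' pair-by-pair heatmap.
#'
#' @param dfc A `dfc_matrix` (supplies the index map).
#' @param selected_features Character vector of selected feature ids.
#' @return Data.frame `band`, `roi_a`, `roi_b`, `count` covering every pair
#'   in the index map (zero counts included).
#' @export
pairwise_discriminative_counts <- function(dfc, selected_features) {
  stopifnot(inherits(dfc, "dfc_matrix"))
  im <- dfc$index_map
  pairs <- unique(im[, c("band", "roi_a", "roi_b")])
  sel <- im[im$feature_id %in% selected_features, , drop = FALSE]
  pairs$count <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(sel$band == pairs$band[i] & sel$roi_a == pairs$roi_a[i] &
          sel$roi_b == pairs$roi_b[i])
  }, integer(1))
  rownames(pairs) <- NULL
  pairs
}

#' Write a dFC feature matrix as TSV
#'
#' Subjects as rows; header of feature ids `band:segN:ROIa-ROIb`.
#' @param x A `dfc_matrix`.
#' @param path File path.
#' @export
write_dfc_matrix <- function(x, path) {
  stopifnot(inherits(x, "dfc_matrix"))
  utils::write.table(x$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
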