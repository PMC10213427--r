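#' Amplitude of low-frequency fluctuations (ALFF) in a band
#'
#' Sum of the spectral amplitude envelope `sqrt(a_k^2 + b_k^2)` over the
#' frequency bins falling inside the band, divided by the number of original
#' (unpadded) time points. Computed on the unfiltered series: band selection
#' happens in the spectral sum, not by pre-filtering.
#'
#' @param x Numeric BOLD series (one unit: voxel or ROI).
#' @param band Named numeric `c(f_low, f_high)` in Hz, or a band name
#'   resolvable by [resolve_band()].
#' @param tr_seconds Repetition time in seconds.
#' @param padded_length Transform length; the default (`NULL`) uses the
#'   series length unpadded. Zero padding refines the frequency grid but
#'   spreads each tone's amplitude into sidelobes, which an amplitude sum
#'   (unlike a power sum) weights noticeably; the fALFF of a pure tone is
#'   1 on the unpadded grid but drops well below it under heavy padding.
#' @return Non-negative amplitude (0 for an all-zero series).
#' @export
alff <- function(x, band, tr_seconds, padded_length = NULL) {
  if (is.null(padded_length)) padded_length <- length(x)
  band <- as_band_limits(band)
  dec <- spectrum_decomposition(x, tr_seconds, padded_length)
  keep <- band_bins(band[["f_low"]], band[["f_high"]], tr_seconds,
                    padded_length)
  amp <- sqrt(dec$a^2 + dec$b^2)
  sum(amp[keep + 1L]) / dec$n_original
}

#' Fractional ALFF (fALFF) in a band
#'
#' Band ALFF divided by full-range ALFF, where the full range is everything
#' from the first non-DC bin up to and including the Nyquist frequency. A
#' normalised measure of how much of a unit's spectral amplitude falls in the
#' band; always in `[0, 1]`.
#'
#' @inheritParams alff
#' @return Fraction in `[0, 1]`.
#' @export
falff <- function(x, band, tr_seconds, padded_length = NULL) {
  if (is.null(padded_length)) padded_length <- length(x)
  band <- as_band_limits(band)
  dec <- spectrum_decomposition(x, tr_seconds, padded_length)
  amp <- sqrt(dec$a^2 + dec$b^2)
  ny <- nyquist(tr_seconds)
  total_bins <- band_bins(0, ny, tr_seconds, padded_length)
  total <- sum(amp[total_bins + 1L])
  if (total <= 0) stop("degenerate series: zero total amplitude",
                       call. = FALSE)
  keep <- band_bins(band[["f_low"]], band[["f_high"]], tr_seconds,
                    padded_length)
  sum(amp[keep + 1L]) / total
}

as_band_limits <- function(band) {
  if (is.character(band)) return(resolve_band(band))
  if (is.numeric(band) && length(band) == 2L) {
    b <- as.numeric(band)
    return(c(f_low = b[1], f_high = b[2]))
  }
  stop("'band' must be a band name or c(f_low, f_high)", call. = FALSE)
}

#' Average voxel time series into ROI time series
#'
#' @param voxel_series Matrix, voxels x time.
#' @param roi_labels Integer ROI label per voxel (row); 0 or NA rows are
#'   treated as background and dropped.
#' @return Matrix, ROIs x time, rows ordered by ascending label and named
#'   by label.
#' @export
roi_average <- function(voxel_series, roi_labels) {
  stopifnot(is.matrix(voxel_series), nrow(voxel_series) == length(roi_labels))
  roi_labels <- as.integer(roi_labels)
  keep <- !is.na(roi_labels) & roi_labels > 0L
  voxel_series <- voxel_series[keep, , drop = FALSE]
  roi_labels <- roi_labels[keep]
  labs <- sort(unique(roi_labels))
  if (length(labs) == 0L) stop("no labelled voxels", call. = FALSE)
  out <- t(vapply(labs, function(l) {
    colMeans(voxel_series[roi_labels == l, , drop = FALSE])
  }, numeric(ncol(voxel_series))))
  rownames(out) <- labs
  out
}

#' Build the subjects x (ROI, band) fALFF feature matrix for a scheme
#'
#' For each subject, each ROI and each band of the scheme, computes fALFF of
#' the ROI series. The Combined scheme concatenates the Slow-5 block before
#' the Slow-4 block, so a 90-ROI cohort yields 180 columns; single-band
#' schemes yield one column per ROI. Column order is frozen in `index_map`
#' so feature ids are stable across runs.
#'
#' @param series List of subject matrices (ROIs x time) or a
#'   `synthetic_cohort`.
#' @param scheme A [band_scheme()] or a scheme label.
#' @param tr_seconds Repetition time in seconds (ignored when `series` is a
#'   cohort, which carries its own TR).
#' @param padded_length Transform length (default: unpadded series
#'   length); see [alff()].
#' @return Object of class `falff_matrix`: list with `values`
#'   (subjects x features), `index_map` (data.frame `feature_id`,
#'   `roi_index`, `band`), `scheme`.
#' @export
build_falff_features <- function(series, scheme = "Combined",
                                 tr_seconds = 2, padded_length = NULL) {
  if (inherits(series, "synthetic_cohort")) {
    tr_seconds <- series$spec$tr_seconds
    series <- series$series
  }
  if (is.character(scheme)) scheme <- band_scheme(scheme)
  stopifnot(inherits(scheme, "band_scheme"), length(series) >= 1L)
  n_rois <- nrow(series[[1]])
  bands <- scheme$bands
  index_map <- do.call(rbind, lapply(seq_len(nrow(bands)), function(bi) {
    data.frame(feature_id = paste0("ROI", seq_len(n_rois), "@",
                                   bands$name[bi]),
               roi_index = seq_len(n_rois), band = bands$name[bi],
               stringsAsFactors = FALSE)
  }))
  values <- t(vapply(series, function(m) {
    stopifnot(nrow(m) == n_rois)
    unlist(lapply(seq_len(nrow(bands)), function(bi) {
      b <- c(f_low = bands$f_low[bi], f_high = bands$f_high[bi])
      vapply(seq_len(n_rois), function(r) {
        falff(m[r, ], b, tr_seconds, padded_length)
      }, numeric(1))
    }), use.names = FALSE)
  }, numeric(n_rois * nrow(bands))))
  colnames(values) <- index_map$feature_id
  structure(list(values = values, index_map = index_map,
                 scheme = scheme$label),
            class = "falff_matrix")
}

#' Write / read a fALFF feature matrix as TSV
#'
#' Subjects as rows, a header row of feature ids of the form `ROIn@band`.
#' @param x A `falff_matrix`.
#' @param path File path.
#' @return `path` invisibly (writer); a `falff_matrix` (reader).
#' @export
write_falff_matrix <- function(x, path) {
  stopifnot(inherits(x, "falff_matrix"))
  utils::write.table(x$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_falff_matrix
#' @param scheme Scheme label recorded on the restored object.
#' @export
read_falff_matrix <- function(path, scheme = "Combined") {
  values <- as.matrix(utils::read.delim(path, check.names = FALSE))
  ids <- colnames(values)
  parts <- regmatches(ids, regexec("^ROI([0-9]+)@(.+)$", ids))
  index_map <- data.frame(
    feature_id = ids,
    roi_index = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    band = vapply(parts, function(p) p[3], character(1)),
    stringsAsFactors = FALSE)
  structure(list(values = values, index_map = index_map, scheme = scheme),
            class = "falff_matrix")
}
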