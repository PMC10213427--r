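#' Canonical synthetic study conditions
#'
#' The reference cohort configuration used throughout the package's
#' validation: a balanced 46 + 46 cohort of 90 regions x 142 time points at
#' TR = 2 s. With `effects = TRUE` it injects the canonical effect pattern
#' — five regions with a Slow-5 fALFF amplitude effect, ten with a Slow-4
#' effect (multiplier 1.5, a moderate effect that separates groups only in
#' combination, as single-region amplitude differences in patient cohorts
#' do), and one Slow-4 connectivity effect between two of the Slow-4
#' regions (sliding-window correlation 0.7 in cases vs 0.1 in controls).
#' Background noise is `noise_sd = 0.5`, half the unit RMS of each band
#' component — a low-noise regime in which recovery of the injected
#' structure is expected. `effects = FALSE` gives the matched null cohort.
#'
#' @param seed Integer seed.
#' @param effects Inject the canonical effect pattern (`TRUE`) or none.
#' @return A [cohort_spec()].
#' @export
#' @examples
#' spec <- study_cohort_spec(seed = 1)
#' length(spec$falff_effects)   # 15
study_cohort_spec <- function(seed = 1L, effects = TRUE) {
  slow5_rois <- c(10L, 20L, 30L, 40L, 50L)
  slow4_rois <- c(5L, 15L, 25L, 35L, 45L, 55L, 65L, 75L, 85L, 90L)
  falff_effects <- if (effects) {
    c(lapply(slow5_rois, function(r) list(roi = r, band = "Slow-5",
                                          multiplier = 1.5)),
      lapply(slow4_rois, function(r) list(roi = r, band = "Slow-4",
                                          multiplier = 1.5)))
  } else list()
  dfc_effects <- if (effects) {
    list(list(roi_a = 15L, roi_b = 25L, band = "Slow-4",
              case_correlation = 0.7, control_correlation = 0.1))
  } else list()
  cohort_spec(n_per_group = 46L, n_rois = 90L, n_timepoints = 142L,
              tr_seconds = 2, falff_effects = falff_effects,
              dfc_effects = dfc_effects, noise_sd = 0.5,
              seed = as.integer(seed))
}
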