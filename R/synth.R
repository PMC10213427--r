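#' Specification of a synthetic case/control BOLD cohort
#'
#' Describes the cohort the generator emulates: a balanced two-group
#' resting-state study with `n_per_group` subjects per group, `n_rois`
#' regional time series of `n_timepoints` samples at repetition time
#' `tr_seconds`. Defaults mirror a typical schizophrenia case/control
#' acquisition: 46 + 46 subjects, 90 AAL cortical regions, 142 retained
#' time points at TR = 2 s.
#'
#' Group effects are injected on top of a common spectral floor:
#' `falff_effects` multiply the amplitude of one region's band-limited
#' component in the case group (so the targeted (ROI, band) fALFF separates
#' the groups), and `dfc_effects` impose a group-specific correlation
#' between the in-band components of a region pair via a shared latent
#' signal mixed with weight sqrt(rho).
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param n_rois Regions per subject (>= 2).
#' @param n_timepoints Samples per series.
#' @param tr_seconds Repetition time in seconds.
#' @param falff_effects List of `list(roi, band, multiplier)`; `multiplier`
#'   scales the case group's in-band amplitude (> 0).
#' @param dfc_effects List of
#'   `list(roi_a, roi_b, band, case_correlation, control_correlation)` with
#'   correlations in `[-1, 1]`.
#' @param noise_sd White-noise standard deviation added to every series
#'   (band components have unit RMS each).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec.
#' @return Object of class `cohort_spec`.
#' @export
#' @examples
#' sp <- cohort_spec(n_per_group = 4, n_rois = 6, seed = 1,
#'                   falff_effects = list(list(roi = 2, band = "Slow-5",
#'                                             multiplier = 2)))
cohort_spec <- function(n_per_group = 46L, n_rois = 90L,
                        n_timepoints = 142L, tr_seconds = 2,
                        falff_effects = list(), dfc_effects = list(),
                        noise_sd = 1, seed = 1L) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid '", field, "': ", msg, call. = FALSE)
  }
  chk(n_per_group >= 2, "n_per_group", "need >= 2 subjects per group")
  chk(n_rois >= 2, "n_rois", "need >= 2 regions")
  chk(n_timepoints >= 4, "n_timepoints", "series too short")
  chk(tr_seconds > 0, "tr_seconds", "must be positive")
  chk(noise_sd >= 0, "noise_sd", "must be non-negative")
  for (e in falff_effects) {
    chk(all(c("roi", "band", "multiplier") %in% names(e)), "falff_effects",
        "each effect needs roi, band, multiplier")
    chk(e$roi >= 1 && e$roi <= n_rois, "falff_effects",
        paste0("roi ", e$roi, " outside 1..", n_rois))
    chk(e$multiplier > 0, "falff_effects", "multiplier must be > 0")
    resolve_band(e$band)   # errors if unresolvable
  }
  for (e in dfc_effects) {
    chk(all(c("roi_a", "roi_b", "band", "case_correlation",
              "control_correlation") %in% names(e)), "dfc_effects",
        "each effect needs roi_a, roi_b, band, case/control correlations")
    chk(all(c(e$roi_a, e$roi_b) >= 1) && all(c(e$roi_a, e$roi_b) <= n_rois),
        "dfc_effects", "roi index outside range")
    chk(e$roi_a != e$roi_b, "dfc_effects", "roi_a must differ from roi_b")
    chk(abs(e$case_correlation) <= 1 && abs(e$control_correlation) <= 1,
        "dfc_effects", "correlations must lie in [-1, 1]")
    resolve_band(e$band)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_rois = as.integer(n_rois),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 falff_effects = falff_effects, dfc_effects = dfc_effects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

## One band-limited component: a sum of n_sin sinusoids at frequencies drawn
## uniformly in the band with uniform random phases, scaled to unit RMS
## (each sinusoid amplitude sqrt(2 / n_sin)).
band_component <- function(band, t_sec, n_sin = 8L) {
  f <- stats::runif(n_sin, band[["f_low"]], band[["f_high"]])
  ph <- stats::runif(n_sin, 0, 2 * pi)
  amp <- sqrt(2 / n_sin)
  colSums(amp * sin(outer(2 * pi * f, t_sec) + ph))
}

#' Generate a seeded synthetic cohort
#'
#' Each regional series is a sum of unit-RMS band-limited oscillatory
#' components — one per N3L band supported by the acquisition — plus white
#' noise. For every `falff_effect` the targeted in-band component is
#' multiplied by the stated factor in cases only; for every `dfc_effect` the
#' in-band components of the two regions are built from a shared latent
#' component mixed with weight sqrt(rho) (group-specific rho), giving an
#' expected in-band correlation of rho. Subjects are ordered cases first
#' (label 1) then controls (label 0). Bit-identical output for identical
#' specs.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: `series` (list of ROI x time
#'   matrices), `labels` (integer vector), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  bands <- n3l_band_table(spec$tr_seconds, spec$n_timepoints)
  t_sec <- (seq_len(spec$n_timepoints) - 1L) * spec$tr_seconds
  n_subj <- 2L * spec$n_per_group
  labels <- rep(c(1L, 0L), each = spec$n_per_group)

  ## effect lookups keyed by band row
  fe_key <- vapply(spec$falff_effects, function(e)
    paste0(e$roi, "@", e$band), character(1))
  fe_mult <- vapply(spec$falff_effects, function(e)
    as.numeric(e$multiplier), numeric(1))

  series <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    is_case <- labels[s] == 1L
    m <- matrix(0, spec$n_rois, spec$n_timepoints)
    ## shared latents for correlated pairs, one per dfc effect
    latents <- lapply(spec$dfc_effects, function(e) {
      band_component(resolve_band(e$band), t_sec)
    })
    for (r in seq_len(spec$n_rois)) {
      for (bi in seq_len(nrow(bands))) {
        bname <- bands$name[bi]
        blim <- c(f_low = bands$f_low[bi], f_high = bands$f_high[bi])
        comp <- band_component(blim, t_sec)
        ## correlated-pair construction replaces the independent component
        for (ei in seq_along(spec$dfc_effects)) {
          e <- spec$dfc_effects[[ei]]
          if (bname == e$band && r %in% c(e$roi_a, e$roi_b)) {
            rho <- if (is_case) e$case_correlation else e$control_correlation
            sgn <- if (r == e$roi_b && rho < 0) -1 else 1
            comp <- sgn * sqrt(abs(rho)) * latents[[ei]] +
              sqrt(1 - abs(rho)) * comp
          }
        }
        mult <- 1
        if (is_case) {
          hit <- fe_key == paste0(r, "@", bname)
          if (any(hit)) mult <- prod(fe_mult[hit])
        }
        m[r, ] <- m[r, ] + mult * comp
      }
      m[r, ] <- m[r, ] + stats::rnorm(spec$n_timepoints, sd = spec$noise_sd)
    }
    series[[s]] <- m
  }
  names(series) <- sprintf("sub-%03d", seq_len(n_subj))
  structure(list(series = series, labels = labels, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic BOLD cohort: ", sum(x$labels == 1L), " cases + ",
      sum(x$labels == 0L), " controls, ", x$spec$n_rois, " ROIs x ",
      x$spec$n_timepoints, " timepoints @ TR = ", x$spec$tr_seconds,
      " s\n", sep = "")
  cat("Injected effects: ", length(x$spec$falff_effects), " fALFF, ",
      length(x$spec$dfc_effects), " dFC\n", sep = "")
  invisible(x)
}

#' Ground-truth table of injected effects
#'
#' Machine-readable record of which features should discriminate the
#' groups in a generated cohort: fALFF effects as `ROIr@band` feature ids
#' and dFC effects as `band:ROIa-ROIb` pair ids (segment-level dFC feature
#' ids share this prefix-free pair label in their index map).
#'
#' @param cohort A `synthetic_cohort`.
#' @return Data.frame `feature_id`, `type` ("falff"/"dfc"),
#'   `expected_direction` ("case>control" or "case<control"); zero rows if
#'   the cohort carries no effects.
#' @export
effect_truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  spec <- cohort$spec
  rows <- list()
  for (e in spec$falff_effects) {
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = paste0("ROI", e$roi, "@", e$band), type = "falff",
      expected_direction = if (e$multiplier > 1) "case>control"
                           else "case<control",
      stringsAsFactors = FALSE)
  }
  for (e in spec$dfc_effects) {
    a <- min(e$roi_a, e$roi_b); b <- max(e$roi_a, e$roi_b)
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = paste0(e$band, ":ROI", a, "-ROI", b), type = "dfc",
      expected_direction = if (e$case_correlation > e$control_correlation)
        "case>control" else "case<control",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(feature_id = character(0), type = character(0),
                      expected_direction = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Expand a ROI-level cohort to voxel level
#'
#' Replicates each regional series over `voxels_per_roi` voxels (optionally
#' adding voxel-level noise), returning per-subject voxel matrices and the
#' voxel-to-ROI label vector — a test bed for [roi_average()] and the
#' volume reader path.
#'
#' @param cohort A `synthetic_cohort`.
#' @param voxels_per_roi Voxels per region.
#' @param voxel_noise_sd Independent noise added per voxel (0 = exact
#'   replication, so averaging recovers the ROI series exactly).
#' @return List with `voxel_series` (list of voxel x time matrices) and
#'   `roi_labels` (integer per voxel).
#' @export
cohort_to_voxels <- function(cohort, voxels_per_roi = 3L,
                             voxel_noise_sd = 0) {
  stopifnot(inherits(cohort, "synthetic_cohort"), voxels_per_roi >= 1L)
  set.seed(cohort$spec$seed + 1L)
  labs <- rep(seq_len(cohort$spec$n_rois), each = voxels_per_roi)
  vs <- lapply(cohort$series, function(m) {
    v <- m[labs, , drop = FALSE]
    if (voxel_noise_sd > 0) {
      v <- v + matrix(stats::rnorm(length(v), sd = voxel_noise_sd),
                      nrow(v), ncol(v))
    }
    rownames(v) <- NULL
    v
  })
  list(voxel_series = vs, roi_labels = labs)
}

#' Write a cohort to a directory of plain-text files
#'
#' One TSV per subject (ROIs as rows, time points as columns), a
#' `labels.tsv` (subject, label) and a `truth.json` with the injected-effect
#' table and the generating spec.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$series)) {
    utils::write.table(cohort$series[[nm]],
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(data.frame(subject = names(cohort$series),
                                label = cohort$labels),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(spec = unclass(cohort$spec),
                            truth = effect_truth_table(cohort)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing per-subject TSVs and `labels.tsv`.
#' @return A `synthetic_cohort` (spec restored from `truth.json` when
#'   present; otherwise a minimal spec is reconstructed with the given TR).
#' @param tr_seconds Fallback repetition time when no `truth.json` exists.
#' @export
read_cohort <- function(dir, tr_seconds = 2) {
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  series <- lapply(lab$subject, function(nm) {
    as.matrix(utils::read.delim(file.path(dir, paste0(nm, ".tsv")),
                                header = FALSE))
  })
  names(series) <- lab$subject
  for (i in seq_along(series)) dimnames(series[[i]]) <- NULL
  tj <- file.path(dir, "truth.json")
  spec <- if (file.exists(tj)) {
    s <- jsonlite::read_json(tj, simplifyVector = TRUE)$spec
    cohort_spec(s$n_per_group, s$n_rois, s$n_timepoints, s$tr_seconds,
                lapply(seq_len(NROW(s$falff_effects)), function(i)
                  as.list(s$falff_effects[i, ])),
                lapply(seq_len(NROW(s$dfc_effects)), function(i)
                  as.list(s$dfc_effects[i, ])),
                s$noise_sd, s$seed)
  } else {
    cohort_spec(n_per_group = sum(lab$label == 1L),
                n_rois = nrow(series[[1]]),
                n_timepoints = ncol(series[[1]]),
                tr_seconds = tr_seconds)
  }
  structure(list(series = series, labels = as.integer(lab$label),
                 spec = spec),
            class = "synthetic_cohort")
}

#' Write a cohort as synthetic 4-D NIfTI volumes plus an atlas
#'
#' Builds one small 4-D volume per subject in which every atlas region is a
#' block of voxels carrying the region's time series (constant across the
#' block), plus a 3-D integer-labelled atlas volume — enough to exercise the
#' volume reader path end to end. Requires the RNifti package.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @param voxels_per_roi Voxels per region along the first axis.
#' @return `dir`, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir, voxels_per_roi = 2L) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI output", call. = FALSE)
  }
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_rois <- cohort$spec$n_rois
  nt <- cohort$spec$n_timepoints
  atlas <- array(0L, dim = c(n_rois, voxels_per_roi, 1L))
  for (r in seq_len(n_rois)) atlas[r, , 1L] <- r
  RNifti::writeNifti(RNifti::asNifti(atlas),
                     file.path(dir, "atlas.nii.gz"))
  for (nm in names(cohort$series)) {
    vol <- array(0, dim = c(n_rois, voxels_per_roi, 1L, nt))
    for (r in seq_len(n_rois)) {
      for (v in seq_len(voxels_per_roi)) {
        vol[r, v, 1L, ] <- cohort$series[[nm]][r, ]
      }
    }
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(1, 1, 1, cohort$spec$tr_seconds)
    RNifti::writeNifti(img, file.path(dir, paste0(nm, "_bold.nii.gz")))
  }
  utils::write.table(data.frame(subject = names(cohort$series),
                                label = cohort$labels),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
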