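---
title: "Multi-frequency dynamic functional connectivity: models and methods"
author: "mfdfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-frequency dynamic functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfdfc)
```

## The problem

Resting-state fMRI produces, for each brain region, a slow fluctuating
BOLD time series. Two families of summaries carry diagnostic signal in
psychiatric case/control cohorts: the *amplitude* of a region's
fluctuations in a frequency band (local activity), and the *time-varying
correlation* between regions (dynamic functional connectivity, dFC).
Conventional analyses use one broad band, 0.01–0.08 Hz. The premise of
this package is that distinct frequency bands carry distinct information,
and that features drawn from two narrower bands jointly covering the
conventional range — then combined — discriminate patients from controls
better than the broad band alone, particularly at short dFC window
widths.

## The N3L frequency ladder

Neural oscillation classes are naturally spaced logarithmically: band
boundaries form a geometric ladder with ratio $e$, so the bands are an
arithmetic progression on the log-frequency axis. We anchor the ladder so
that band *Slow-k* spans

$$\mathrm{Slow\mbox{-}}k \;=\; \left[e^{-(k-0.5)},\; e^{-(k-1.5)}\right]\ \mathrm{Hz}.$$

At TR = 2 s the Nyquist frequency is $1/(2\,\mathrm{TR}) = 0.25$ Hz and,
with a minimal reliable frequency of $7.32\times10^{-4}$ Hz, the
investigable range splits into seven bands (Slow-8 … Slow-2), the top and
bottom bands clipped to that range:

```{r bands}
n3l_band_table(2, 142)
```

Two rounding quirks are worth documenting. The ladder value
$e^{-2.5}=0.082085$ is usually quoted as 0.0820 although it rounds to
0.0821, and $e^{-5.5}=0.004087$ is usually quoted as 0.0040; the package
reproduces the ladder, not those quotations. The conservative lowest
frequency after padding a 142-point series to 4096 samples is
$1/(4096\cdot\mathrm{TR}/2) = 2.44\times10^{-4}$ Hz. Slow-5
(0.0111–0.0302 Hz) and Slow-4 (0.0302–0.0821 Hz) together approximate the
conventional band; the *Combined* scheme concatenates features from both,
the *Conventional* scheme is the literal 0.01–0.08 Hz mask (not a union
of ladder bands).

## Spectral machinery

All spectral operations express the (optionally zero-padded) series as
$x(t)=\sum_k a_k\cos(2\pi f_k t)+b_k\sin(2\pi f_k t)$ on the grid
$f_k = k/(M\,\mathrm{TR})$ with $M$ the transform length.

**Band-pass filter.** `bandpass()` applies an ideal rectangular mask: pad
to $M$ (default 4096), zero all coefficients outside $[f_{low}, f_{high})$
(conjugate-symmetrically; DC always removed; a band touching Nyquist keeps
the Nyquist bin), invert, truncate. Band edges are half-open on the grid
so adjacent ladder bands stay disjoint. Two numerical consequences are
accepted rather than hidden: the rectangular mask rings near the series
edges (tests trim edges; no taper is applied, keeping the filter exactly
invertible over bands), and the pad-then-truncate round trip is not a
projection, so strict idempotence holds only at $M = N$. The series mean
is subtracted before padding — after zeros are appended the mean is no
longer confined to the DC bin, and without demeaning a constant series
would leak into low-frequency bands.

**fALFF.** Band amplitude is
$\mathrm{ALFF}(b)=\sum_{k: f_k\in b}\sqrt{a_k^2+b_k^2}\,/\,N$ and
$\mathrm{fALFF}(b)=\mathrm{ALFF}(b)/\mathrm{ALFF}(0\!-\!f_{Nyq})$, the
denominator excluding DC. fALFF is computed on the *unfiltered* series —
band selection happens inside the spectral sum — and, by default, on the
unpadded transform ($M=N$). The default matters: zero padding spreads
each tone into Dirichlet sidelobes, and because fALFF sums *amplitudes*
(not powers) the sidelobe tail is heavy — the fALFF of a pure in-band
tone drops from exactly 1 at $M=N$ to roughly 0.75 at $M=4096$. The
unpadded amplitude sum keeps fALFF of on-grid tones at its nominal 0/1
extremes and the white-noise expectation at the bandwidth fraction
(≈ 0.21 for Slow-4 at TR = 2 s). Padding remains available as a
parameter.

## Sliding-window connectivity

For the regions selected in stage one, band-passed series are summarised
by windowed Pearson correlations with window width $w \in \{15, 20, 25,
30\}$ TRs and step 5 TRs (both configurable): windows start at sample 1,
advance by the step, and trailing samples not covered by a full window
are dropped, giving $\lfloor (N-w)/s\rfloor + 1$ segments — 26/25/24/23
at $N=142$. Each (band, segment, unordered region pair) correlation is
one feature; vectorisation order is frozen (band-major, then segment,
then upper-triangle row-major) and written into the index map so feature
ids are stable across runs. A window with zero variance in either series
has no defined correlation; it is recorded as 0 with a warning rather
than silently dropped. In the Conventional scheme the same per-band
region lists are used but the series are filtered with the conventional
mask. Per-band window widths may differ (`mixed_window_features()`), in
which case per-band segment counts differ and blocks are concatenated
band-wise.

## Feature selection and classification

**Ranking.** Recursive feature elimination under a linear support vector
regression: z-score the columns, fit, delete the feature with the
smallest absolute coefficient, refit, until all features are rated; the
elimination order reversed is the ranking, and the recorded weight is the
absolute coefficient at elimination (its raw scale — no normalisation is
applied). Ties break by ascending column index. One feature per round is
the default; `elim_step` (and, inside cross-validation folds, a halving
schedule) trades granularity for speed on very wide matrices. The
`cv_folds` argument is carried to downstream sweeps; the ranking itself
is a deterministic function of the data — the cross-validated part of
the workflow is the top-N sweep that chooses how many ranked features to
keep.

**Top-N sweep.** For each candidate N the top-N features are classified
by repeated cross-validation and the N maximising mean accuracy defines
the selected ("abnormal") set. When several N tie at the maximum the
*largest* is taken: the discriminative set errs on inclusion, since at
low noise a single strong feature can already saturate the accuracy
curve and a parsimonious tie-break would collapse the set to one region,
defeating the purpose of delimiting the full abnormal set.

**Classifier.** A C-classification SVM grid-searched over 22
combinations — linear with $C\in\{1,10,100,1000\}$, polynomial with
$C=1$, degree 2 or 3, radial with $C\in\{1,10,100,1000\}\times\gamma\in
\{1,0.1,0.01,0.001\}$ — under repeated stratified k-fold
cross-validation (default 10-fold; 50 repeats for final reports, fewer
in the orchestrated fit, see below). Per repeat the fold assignment is
reshuffled from the seed, each combination's held-out predictions are
collected, the combination with the best CV accuracy is chosen, and that
combination's held-out confusion yields ACC/precision/recall/f1; AUC
uses the continuous decision scores, never thresholded labels, with a
fixed orientation (higher = case) so chance data yields chance AUC.
Features are z-scored with training-fold statistics before every fit —
margin-based estimators need a common scale for the C grid to be
comparable.

**Leakage.** Ranking features on all subjects and then cross-validating
the selected columns is optimistic: the selection has seen the test
folds. By default the reported classification re-selects features inside
every training fold (`select_in_train = TRUE`, a halving RFE down to the
sweep's chosen N), so held-out metrics are honest; the rank-once
workflow remains available behind the flag because it is the common
exploratory practice and is what selection-curve figures depict. The
package's null-calibration tests verify that the default mode scores at
chance on effect-free data while the same data would score above chance
under rank-once selection.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the pipeline
assumes, not raw physiology. Each regional series is a sum of unit-RMS
band-limited components — one per ladder band in range, each a sum of
eight sinusoids at uniformly drawn in-band frequencies with uniform
phases — plus white noise. Sums of sinusoids are used because their
spectral amplitude, hence fALFF, is analytically predictable. Amplitude
effects multiply a (region, band) component in cases only; connectivity
effects build the two regions' in-band components from a shared latent
component mixed with weight $\sqrt{\rho}$, giving expected in-band
correlation $\rho$ with group-specific values. Labels are 1 (case) and
0 (control), cases first. Everything is a deterministic function of the
spec, including its seed.

The canonical study conditions (`study_cohort_spec()`) mirror a typical
acquisition: 46 + 46 subjects, 90 regions, 142 time points at TR = 2 s.
The injected pattern is five Slow-5 regions and ten Slow-4 regions with
amplitude multiplier 1.5, plus one Slow-4 pair at correlation 0.7
(cases) versus 0.1 (controls), over background noise at half the band
component RMS (`noise_sd = 0.5`). The multiplier is deliberately
moderate: single-region amplitude differences in patient cohorts do not
individually separate groups, so a realistic regime is one where the
accuracy curve keeps rising until most affected regions are included
rather than saturating on the first feature.

What the generator does *not* emulate — hemodynamic response shapes,
scanner drift, motion, spatially correlated noise, voxel-level structure
(regions are generated directly; a voxel expansion exists only to
exercise the averaging path) — bounds what passing tests show: they
validate the pipeline's statistical machinery and its recovery/null
behaviour, not robustness to real acquisition artefacts, which are
assumed to be removed upstream.

## Orchestration, problem sizes, degenerate inputs

`mfdfc()` chains the two stages and returns a classed fit with
`print`/`summary`/`coef`/`plot`/`predict` methods; `run_falff_stage()`
and `run_dfc_stage()` expose the stages individually, and
`read_bold_nifti()` feeds the same pipeline from preprocessed 4-D
volumes (only initial-volume removal, default 10, is re-applied —
realignment, nuisance regression and smoothing are deliberately out of
scope). Defaults in the orchestrated fit are sized so that a full
synthetic run at the canonical conditions completes on a single CPU in
minutes: 10 CV repeats for reported metrics (the standalone
`svm_classify()` defaults to 50), a single repeat inside sweeps, dFC
sweep over N = 2, 4, …, 60, and block elimination (5 per round) when
ranking the dFC matrix, whose width (1430 columns at width 15) makes
one-at-a-time elimination disproportionate. All of these are arguments,
not constants. The validation battery likewise states its sizes
explicitly: oracle equivalence on 100 random instances, amplitude-effect
recovery over 10 seeds at full cohort scale, pair-recovery over 3 seeds,
null calibration at 5 repeats with the full 22-point grid.

Degenerate inputs have defined behaviour rather than silent defaults:
an all-zero series has ALFF 0 but fALFF errors ("degenerate series"); a
zero-variance window records 0 with a warning; undefined
precision/recall (zero denominators) are reported as `NA`, not 0; a
band list with fewer than two selected regions contributes no pairs and
is skipped with a warning; more folds than the minority class errors.

## Known limitations

The ideal mask's edge ringing biases windowed correlations near the
series boundary slightly; tapered or FIR alternatives are out of scope.
The top-N sweep on the full cohort is an exploratory curve and its
accuracies should not be quoted as performance — use the
leakage-free report. The generator's stationary group-specific
correlations realise dFC differences through window-scale sampling
variability, not through explicit state switching; clustering of dFC
states is likewise out of scope. Published accuracies for particular
patient cohorts depend on those cohorts and cannot be verified from
synthetic data; this package verifies every structural and statistical
property of the method instead.
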