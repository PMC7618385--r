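---
title: "Quantifying spontaneous calcium activity in the developing cochlea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spontaneous calcium activity in the developing cochlea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cochleaCa)
```

## The measurement problem

Before hearing onset, the mouse cochlea generates spontaneous Ca²⁺ activity
in three interacting cell populations: inner hair cells (IHCs) fire
Ca²⁺-dependent action potentials, singly or as coordinated groups of
neighbours; non-sensory supporting cells produce regenerative intercellular
Ca²⁺ waves that spread across the epithelium, elongated along the cochlear
coil; and the spiral ganglion neuron (SGN) terminals contacting each IHC
follow their presynaptic cell's activity. Two-photon imaging of
GCaMP6f-expressing cochleae in live, anaesthetized pups records this
activity as single-channel 16-bit time-lapse stacks, from which the
scientific quantities of interest — transient frequencies and durations,
event coordination across the IHC row, wave morphometry and kinetics, and
the correlation structure of neighbouring cells — must be extracted.

cochleaCa implements that extraction as a fully automated, testable
pipeline, together with a forward model that simulates all three scene
types with exact ground truth. Every estimator in the package is validated
by recovering known simulated quantities; the test suite and
`scripts/acceptance.R` run those recoveries end to end.

## Pipeline

The processing chain is, in order:

1. **Frame triage.** A sharpness score per frame (variance of a discrete
   Laplacian normalized by squared mean intensity) is compared with a
   rolling median (window 101 frames). Frames below `0.35 x` the local
   median are flagged as out of focus (typically breathing-induced
   defocus) and replaced by the last in-focus frame, so the frame count —
   and hence timing — is never altered. The replaced samples are marked as
   gaps in every trace and linearly interpolated. The threshold sits
   deliberately between two regimes measured on simulated movies: large
   coordinated transients raise the mean intensity and depress the
   normalized score by up to ~2x, while genuine defocus (blur SD 4 px)
   depresses it by more than an order of magnitude. A 0.6x threshold —
   the first value we tried — flagged strong activity as defocus.

2. **Denoising.** A separable Gaussian with FWHM 2 px per axis. By default
   the chain applies the spatial axes only: on a 30 Hz recording, temporal
   smoothing broadens shot-noise excursions to 0.2–0.5 s, exactly past the
   200 ms width criterion used for transient detection, and an automated
   pipeline has no human curator to veto them (measured: ~1.5 false peaks
   per trace per 10 min with temporal smoothing, none without). The full
   3-D filter remains available (`gaussian_denoise(movie, 2, 2)`).

3. **Drift correction.** Rigid integer translation per frame by phase
   correlation against a running template (median of the first 30
   registered frames, refreshed every 100 frames). Two safeguards matter
   in this preparation: the correlation peak is searched only within 5 px
   of the previous frame's shift, because the near-periodic row of somata
   produces correlation peaks at lattice offsets (~ soma spacing) that an
   unconstrained argmax occasionally wins; and the estimated shift series
   is median-filtered over 5 frames, because genuine drift is a slow
   staircase while bright transients cause single-frame estimate blips.
   After registration the global mean is rescaled to equal the input mean
   exactly. Rigid translation is a deliberate simplification: in the small
   apical-coil fields analysed here, rigid motion dominates, and non-rigid
   registration is out of scope.

4. **Segmentation.** Three workflows:
   - *IHC somata*: Otsu threshold on the average image, distance-transform
     watershed to split touching cells, erosion by 1–3 px to limit
     cross-contamination. Externally supplied label masks (e.g. manually
     curated) are authoritative and only receive the erosion. Note that
     erosion is specified in pixels; it is meaningful at the instrument's
     native ~0.5–1 µm pixels and will destroy somata if applied to heavily
     binned data.
   - *Supporting-cell waves*: per-pixel dF/F₀ (temporal-median baseline),
     2x spatial binning, binarization, per-frame watershed splitting from
     smoothed distance-map maxima, and overlap linking across frames into
     3-D (y, x, t) labels. Components spanning under 2 frames or never
     reaching 150 µm² are discarded — the latter removes transients
     confined to individual isolated cells, which belong to the
     single-cell workflow, not the wave analysis. The default threshold is
     half of a robust wave-amplitude estimate (the 90th percentile of
     supra-noise dF/F₀ voxels): a half-maximum boundary, consistent with
     how wave duration is defined. A plain Otsu threshold is structurally
     unreliable here — waves occupy 1–3% of voxels, so Otsu splits either
     the background class or the wave plateau itself, and the original
     analysis thresholded manually; the config accepts an explicit
     `threshold` for exactly that reason.
   - *SGN terminals*: white tophat (disc radius 10–20 px) to suppress
     smooth background, Otsu on the tophat response, watershed from
     smoothed intensity maxima to split touching puncta, and a size gate.

5. **Terminal-to-IHC assignment.** Nearest IHC by centroid-to-mask
   distance; when the two nearest IHCs are within 2 µm of one another the
   terminal goes to the one whose trace correlates best with the
   terminal's (Pearson), with ties falling back to proximity and flagged.
   Terminals are annotated modiolar / pillar / middle by the sign of their
   perpendicular offset from the IHC-row polyline, with "middle" inside
   one third of the IHC's equivalent radius. Synthetic scenes carry no
   anatomy, so which geometric side is called "pillar" is a configuration
   flag tied to the polyline's traversal direction.

6. **dF/F₀ and detection.** Per-ROI pixel-average traces are normalized by
   a sliding-percentile baseline (8th percentile over 30 s), which tracks
   slow drift while ignoring transients. Candidate peaks are local maxima
   of the rolling-median-detrended trace selected by a prominence floor
   (1.5 SD); a candidate is accepted only if its amplitude exceeds 2 SD of
   the detrended trace and its interpolated full width at half maximum
   exceeds 200 ms. Two measurement choices matter:
   - Amplitude and the half-maximum level are referenced to the
     rolling-median baseline (the zero of the detrended trace), not to a
     local pre-peak minimum. With a local-minimum reference the half level
     of a noise excursion drops below ~1 SD and ordinary noise passes both
     criteria (tens of false peaks per 10-minute trace at realistic SNR).
   - The apex height and the width are estimated on a matched-filtered
     copy of the trace (Gaussian kernel, FWHM equal to the 200 ms minimum
     width), and the kernel width is deconvolved from the measured width
     in Gaussian quadrature. On the raw trace, the local maximum rides the
     maximum of the noise (overstating wide sub-threshold transients by
     about one noise SD) and noise dips through the half level truncate
     measured widths; the matched estimate carries several-fold less noise
     and the deconvolution is exact for Gaussian transients.
   Accepted peaks closer than 2 s within one trace collapse to the larger
   peak. Successive same-cell transients inside the 2-s grouping window
   are not resolvable as separate events in any case, and without this
   rule noise shoulders riding a decay are re-detected (~2 detections per
   true transient at SNR 5). These rules replace the manual curation step
   of an interactive workflow.

7. **Event grouping.** Peaks from any cells chain into one event when
   linkable through steps of at most 2 s (transitive closure; union-find
   over time-sorted neighbours). Within a temporal group, participants are
   ordered along the row polyline and split where more than 4
   non-participating cells separate consecutive participants. Events are
   classified single (1 cell), two-cell (2) or multiple (>= 3); two-cell
   events stay in the table and in frequency counts but are excluded from
   the single/multiple percentages, limiting the impact of coincidental
   co-activation. Chaining (rather than requiring all pairs within the
   window) matches the propagating character of coordinated events; a
   brute-force transitive-closure oracle in the test suite verifies the
   implementation exactly on 1000 random instances. SGN terminals of one
   IHC group with a 1-s window and no spatial splitting.

8. **Frequencies and the 5-minute rule.** Frequency is count divided by
   total valid (non-gap) duration, in min⁻¹. Recordings with less than
   5 min of valid time return `NA` — a "not evaluable" marker, never zero.
   Traces stitched across repeated recordings of one field accumulate
   valid time per cell, so partially tracked cells are gated correctly.

9. **Wave morphometry.** Per-frame area (binned-pixel count times the
   squared effective pixel size), equivalent radius `r(t) = sqrt(A/pi)`,
   expansion speed as the least-squares slope of `r(t)` from onset to
   maximal area and contraction speed from maximal area to offset
   (onset/offset at 10% of maximal area); wave FWHM from the pixel-average
   dF/F₀ trace over the maximal-area footprint; longitudinal and radial
   extents as peak-to-peak projections of that footprint onto the local
   polyline tangent (smoothed over +-2 segments) and its normal. The
   equivalent-radius slope is this package's declared convention for
   expansion/contraction speed — boundary-front speed is a plausible
   alternative and would differ for strongly anisotropic waves by a
   direction-dependent factor. Manually outlined 2-D waves join frequency
   and maximal-extension statistics but carry no kinetics.

10. **Correlation structure.** Pairwise Pearson correlations of detrended
    traces over overlapping valid samples, gated at 5 min of simultaneous
    recording. Averages and SDs of correlation coefficients go through
    Fisher's z-transformation: `z = arctanh(r)`, `avg(r) = tanh(mean(z))`,
    `SD(r) = tanh(sd(z))` (sample SD; the n-1 choice is ours, the source
    convention being unstated). Correlation versus distance uses 10 µm
    bins, Fisher-averaged per bin, fitted with `r(d) = A exp(-d/lambda)`
    in the r domain by nonlinear least squares (log-linear start values);
    profiles without measurable decay are flagged flat rather than
    force-fitted. Slope comparisons between linear fits use a two-tailed
    t-test on the difference with the estimated slope variances and
    Welch–Satterthwaite degrees of freedom, Bonferroni-corrected; group
    comparisons route through Shapiro–Wilk screening to one-way ANOVA +
    Tukey or Kruskal–Wallis + Dunn (Bonferroni), and the report states the
    route taken.

## The forward model

`scene_config()` + `generate_ihc_scene()` / `generate_supporting_scene()` /
`generate_sgn_scene()` render movies with exact ground truth for every
quantity the pipeline estimates. All randomness flows from one seeded
generator per scene; identical configurations give bit-identical movies.

Key modelling choices, all configurable:

- **Geometry.** The IHC row is a circular arc (the apical coil's
  curvature), somata are ellipses (default 4.5 x 3.2 µm semi-axes)
  spaced equally by arc length with small positional jitter; placement
  retries jitter a bounded number of times and fails loudly if somata
  cannot avoid overlap. SGN terminals are 1.5 µm discs ringed around
  their parent soma, 1 to 8 per IHC (clipped Poisson, mean 3.3), placed
  with a 2 µm clearance so each punctum is optically resolvable; for
  crowded somata the placement falls back to an even angular grid where
  puncta may touch, as they do in reality.
- **Transients.** Difference of exponentials with rise 0.1 s and decay
  0.7 s (GCaMP6f-like; the source workflow reports no kernel, so these
  are simulator defaults). Events arrive as a Poisson process at
  0.8 peaks/cell/min; each event recruits a contiguous block of cells
  whose length is drawn from a configurable distribution (default: 25%
  single cells, a small two-cell share, and coordinated blocks of ~7
  cells), with peak-time jitter of SD 0.3 s (truncated at 0.9 s) inside a
  block. Block clipping at the row ends is compensated in the event rate,
  so the expected total peak count is exactly rate x cells x duration.
- **Waves.** Ellipses whose long axis follows the local row tangent,
  axis ratio 2:1 by default, equivalent radius growing at 10 µm/s and
  shrinking at 5 µm/s, maximal radii 15–30 µm, plateau amplitude 1.0
  dF/F₀ with a steep (5% of radius) soft edge. Waves leaving the field
  are clipped and flagged.
- **Noise.** Poisson shot noise on baseline-plus-signal photon counts
  (baseline 100 counts in labelled structures, 10 in background) plus
  Gaussian read noise calibrated so a soma-average trace reaches a target
  SNR (amplitude over trace noise SD; default 8, typical of somatic
  GCaMP6f imaging). The in vivo dF/F₀ amplitude scale is unreported in
  the source data, so amplitudes are free parameters (default mean 1.0,
  CV 0.15, log-normal).
- **Frame rates.** 30 Hz for IHC/SGN scenes (resonant-scanner class
  acquisition) and 10 Hz for the slower wave scenes.
- **Artifacts.** `inject_artifacts()` adds breathing-type defocus
  (Gaussian blur of listed frames) and lateral drift (cumulative integer
  translation), logged exactly, so triage and registration can be tested
  for neutrality: a corrupted scene must yield the same event count as
  its clean twin after the chain.
- **Correlated traces.** `simulate_correlated_traces()` draws Gaussian
  traces with correlation `exp(-d/lambda)` via a Cholesky factor. It
  exists because event-block co-participation schemes have no closed-form
  correlation length; the Cholesky construction gives the
  correlation-versus-distance estimator a known truth to recover.

What the simulator does *not* model — optical point-spread functions,
autofluorescence textures and vasculature shadows, z-drift and non-rigid
tissue deformation, photobleaching, and the full morphological diversity
of real somata — bounds what passing tests demonstrate: they validate the
estimators' arithmetic and their robustness to shot noise, defocus and
lateral drift at realistic rates, not robustness to every artifact of
live-animal imaging. Real recordings additionally pass through judgement
steps (mask curation, event review) that the automated defaults replace
with fixed rules.

## Numerical choices and degenerate inputs

- Rolling percentile baselines are evaluated on a strided grid (1/20 of
  the window) and linearly interpolated; F₀ is floored at 1% of the trace
  median.
- Gaussian filtering renormalizes its kernel at the array edges, so
  constants are preserved exactly and the movie mean is unchanged.
- FWHM half-crossings are linearly interpolated between samples; a peak
  whose trace never drops below the half level on one side is rejected
  rather than given an arbitrary width.
- Degenerate wave limbs (fewer than two frames on a side of the maximum)
  give `NA` speeds, never zero; a constant-zero wave trace is an error.
- Empty wave segmentations are valid results (no waves), but an IHC or
  terminal segmentation with zero ROIs is an error — those workflows are
  meaningless without cells.
- Ties in the correlation tie-break assign to the nearer IHC and are
  flagged.

## Problem sizes used in tests

The validation scenes are sized to exercise the estimators well while
keeping a full test run comfortable on a laptop: event recovery uses one
20-cell, 10-minute scene at 30 Hz (about 190 ground-truth peaks); wave
recovery accumulates 50+ unclipped waves over a handful of 2.5-minute
epithelium fields; correlation-length recovery uses 36 cells at 8 µm
spacing over 5+ minutes; the preprocessing-neutrality check runs a
12-cell, 3-minute scene twice (clean and corrupted). Larger scenes change
none of the estimators, only the statistical resolution of the checks.

## Known limitations

- Segmentation replaces the trained-model-plus-curation workflow with
  classical operators; on real data the intended entry point is an
  externally curated mask layer (`segment_ihc(masks = ...)`), with the
  classical fallback for unsupervised runs.
- Drift correction is rigid and integer-valued; sub-pixel or non-rigid
  motion leaves residual trace noise at ROI edges.
- The wave threshold default assumes waves are the brightest extended
  structures in the dF/F₀ movie; fields dominated by other bright
  dynamics need an explicit threshold.
- Frequencies assume stationarity across stitched recordings; no
  correction is attempted for slow rundown within a session.
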