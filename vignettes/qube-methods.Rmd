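---
title: "Quantifying myocardial blush: the QuBE pipeline, its simulator, and its limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myocardial blush: the QuBE pipeline, its simulator, and its limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qube)
```

## The measurement problem

After primary PCI for myocardial infarction, restored flow in the
epicardial artery does not guarantee restored perfusion of the muscle
itself. On a coronary angiogram, tissue perfusion shows as *myocardial
blush*: a faint, diffuse opacification of the myocardium as contrast
passes through the capillary bed. Clinically it is graded visually
(MBG 0-3, from no blush to normal blush), a coarse and
observer-dependent scale. QuBE-style quantification replaces the visual
grade with a scalar computed from the angiographic run itself: the
average contrast intensity inside a region of interest (ROI) is tracked
frame by frame, and the score is the maximum rise plus the maximum fall
of that blush curve over the run.

The difficulty is that blush is a weak, mid-spatial-frequency signal
superimposed on much stronger structures: the contrast-filled arteries,
the diaphragm edge, the catheter, plus cardiac motion and operator
panning. This package implements the full measurement chain, a
synthetic angiogram generator with known ground truth, and the
statistics used to ask whether the score tracks perfusion — including
the failure modes of the approach.

## The pipeline

For each frame, in order:

1. **Contrast inversion.** Iodinated contrast attenuates x-rays, so
   contrast-dense tissue is dark. Frames are inverted once
   (`global_max - value`, with the maximum taken over the whole run) so
   that contrast density is positive and "brightest" means
   "most contrast". Published descriptions of the native software leave
   polarity handling implicit; an explicit global inversion is the one
   choice that keeps inter-frame differences intact.
2. **Background estimation.** A square median filter (default
   35 × 35 px) estimates the large-structure background; the output
   pixel sits at index `floor(side/2)` of the window so the even
   comparison sizes (20, 50) are honoured, and borders use edge
   replication (a constant border would itself create a bright residual
   rim that the brightest-pixel rule would then pick up). Windows with
   an even pixel count take the midpoint of the two central order
   statistics.
3. **Subtraction.** `residual = frame - background`, clipped below at
   zero: a background brighter than the frame carries no contrast
   information, and clipping keeps blush values non-negative.
4. **Panning correction** (fixed ROIs only). Operator table motion is
   modelled as a per-frame integer translation, estimated by maximizing
   normalized cross-correlation with the first frame over a ±20 px
   search box, computed over the frame overlap. Ties break to the
   smallest offset norm, then row-major order; shifts with constant
   overlap are excluded (a fully constant frame yields offset (0, 0)).
   The ROI is shifted by the estimated offset. When a per-frame ROI
   track is supplied the correction is disabled — the track already
   encodes the motion.
5. **Blush value.** The residual is mean-smoothed with a 5 × 5 window
   and the frame's blush value is the mean of the `k` brightest
   smoothed pixels inside the ROI, with
   `k = max(10, ceiling(2% of ROI area))`. The "few brightest pixels"
   rule is under-specified in the published description of the native
   software; all three knobs (`top_fraction`, `min_top_pixels`,
   `smoothing_side_px`) are explicit options, and the defaults were
   chosen to be robust to single-pixel noise while remaining local.
   Note the mean of the `k` largest values is well defined under ties,
   so no tie-breaking policy is needed.
6. **Score.** With blush curve `v`, the maximum increase is
   `a = max over i<j of (v_j - v_i)` (floored at 0), the maximum
   decrease `b` likewise with the sign flipped, and the QuBE score is
   `a + b`. The rise and fall are global (over all ordered frame
   pairs), not consecutive-frame differences: the rises and falls the
   score is meant to capture span many frames, and the pairwise
   definition is the only parameter-free reading. No curve smoothing is
   applied before scoring. The score is invariant under adding a
   constant to the curve, scales linearly under positive scaling, and
   swaps `a`/`b` under time reversal.

ROIs are simple polygons in 0-based (row, col) coordinates with pixel
centers on the integer grid; rasterization uses the even-odd rule with
boundary pixels included — a deterministic convention that an
exhaustive point-in-polygon oracle can check pixel for pixel.

## The simulator

No angiograms ship with this package (no suitable public dataset with
MBG labels exists), so `simulate_sequence()` builds scenes with known
ground truth. A run is composited in a reference pose as

```
background - vessels * g(t) - diaphragm - catheter - blush * h(t)
```

(dark structures on a bright field, raw polarity), rigid-warped per
frame, and degraded with additive Gaussian noise. The components:

* **Blush kinetics**: a gamma-variate bolus curve
  `h(t) = A ((t-t0)/tp)^alpha * exp(alpha (1 - (t-t0)/tp))`, the
  standard indicator-dilution model, normalized so `h(t0+tp) = A`
  exactly. Defaults: arrival 1 s, time-to-peak 1.6 s, `alpha = 3`,
  sampled at 12.5 frames/s for 60 frames. The blush is a spatial
  Gaussian of scale 45 px.
* **Vessel tree**: 2-4 levels of quadratic Bézier branches with
  Gaussian cross-sections (root scale 16 px tapering to 6 px),
  opacified by an earlier, narrower gamma-variate transit. Any
  curvilinear dark structure suffices to exercise the edge-artifact
  behaviour of the median filter.
* **Diaphragm**: a soft logistic edge; **catheter**: a thin static
  curve near the frame border.
* **Motion**: a cardiac sinusoid (period 0.8 s, 4 px translation,
  1.5° rotation about the image centre) plus a linear panning drift
  (0.3 px/frame), applied as a rigid warp with bilinear interpolation
  and edge replication. Sub-pixel motion is intended: it stresses the
  integer panning correction. Real cardiac motion includes
  non-isotropic contraction; rigid motion is a deliberate
  simplification that keeps the ground-truth ROI track exact, and it is
  a fidelity limit of every motion result below.
* **Noise**: additive Gaussian (sigma 2 on a background of 160).
  Frames are kept in floating point by default; `quantize = TRUE`
  rounds to the integer grid as a digital detector would (the CLI does
  this before writing files, since the storage formats are
  integer-sampled by design to guarantee lossless round trips).

The ground truth carries `h` sampled at frame times, per-frame motion
parameters, structure masks, and the exact image of the reference ROI
under each frame's motion — the "perfectly motion-corrected observer".

### Scene geometry and amplitudes

The reference ROI is a square (half-side 45 px) centred on the blush,
placed in the distal perfusion territory away from the proximal vessel
tree — as the grading cardiologist would place it, and as the method
requires: an ROI straddling a major artery measures artery transit, not
blush. Grade-conditional blush amplitudes are 0/20/40/60 (MBG 0-3) with
15% log-normal per-patient jitter in `associated` mode, against a
vessel contrast of 90: blush at the top grade is roughly two-thirds of
arterial contrast, consistent with "normal blush comparable to the
reference territory", and grade 0 is strictly no blush. In `null` mode
amplitudes are drawn uniformly over the same range irrespective of
grade, giving an exact null for type-I calibration. These choices were
fixed from the scene design, not fitted to any published score scale;
absolute score values are therefore not comparable to published
tables — only orderings and associations are.

### What the simulator does not capture

Physically accurate x-ray transport, 3-D anatomy and foreshortening,
deformable myocardial motion, Poisson noise, detector blur, and
inter-hospital acquisition differences. Passing tests on this simulator
show the pipeline is internally correct and that the claimed mechanisms
(kernel-size sensitivity, bifurcation spikes) operate as described;
they do not show the score is clinically valid on real angiograms,
where reported findings on its association with visual grading are
mixed.

## The experiments

* **Kernel comparison** (`kernel_comparison_experiment()`): every
  patient scored under kernels 20/35/50 px, summarized as median (IQR)
  per MBG grade (inclusive linear-interpolation quartiles), with
  Spearman rank association and Kruskal-Wallis differences per kernel.
  The mechanism: a median window smaller than the blush scale absorbs
  the blush into the background, so with the default 45 px blush,
  kernel 20 strictly under-scores kernel 35 at every perfused grade.
* **Motion experiment** (`motion_experiment()`): native fixed-ROI
  curves vs per-observer corrected curves (observer = ground-truth
  track plus Gaussian vertex jitter), with per-observer median/range of
  the curve correlation, Wilcoxon signed-rank on paired scores, and
  Lin's concordance between observers' corrected scores.
* **Bifurcation scenario** (`bifurcation_scenario()`): the one
  situation where motion correction demonstrably matters — a fixed ROI
  adjacent to, but not containing, a bifurcation whose edge-artifact
  cluster swings in and out with the cardiac cycle, spiking the native
  curve while the tracked ROI stays clean. Because the simulator's
  motion is globally rigid, integer panning correction could absorb the
  cardiac translation here — something it cannot do for genuinely local
  cardiac motion — so this scenario is evaluated with panning
  correction off.

## Statistical conventions

Mid-ranks for all ties; Spearman p-values from the t approximation
(method recorded in the output); Kruskal-Wallis with tie correction and
the `H = 0, p = 1` convention when all values are identical; Wilcoxon
signed-rank with zero differences dropped (count logged), exact
two-sided p by enumerating the signed-rank distribution for n ≤ 25
(dynamic programming over doubled ranks, so mid-ranks stay exact) and
the tie-corrected normal approximation with continuity correction
above; Lin's concordance with population (n-denominator) moments per
the original estimator, with the sample variant as an option. Undefined
statistics (constant inputs) are reported as flagged missing values,
never coerced to 0, and downstream summaries skip them with a logged
count. The 0.05 threshold is reported alongside results, never used to
suppress them.

## Numerical and design choices

* Median filtering uses an exact sliding-histogram algorithm over
  rank-transformed values, so arbitrary float frames get exact medians
  at any kernel size, verified against an exhaustive per-window oracle.
* The NCC search evaluates every integer shift in the box; per-shift
  means and variances come from summed-area tables. Near-constant
  overlaps (relative variance below 1e-9) are treated as undefined
  rather than amplified.
* Frame-rate precedence on read: file metadata, then the caller's
  override, then 12.5 Hz, the standard cine rate assumed throughout.
* Image stacks are ordered lexicographically by filename
  (locale-independent), and written stacks carry a JSON sidecar with
  the frame rate.
* DICOM support is a minimal XA reader/writer (uncompressed
  little-endian syntaxes, pixel data only), round-trip exact and
  cross-checked against an independent DICOM toolkit in the tests.
* Intensities become floating point at read time; the original bit
  depth is recorded but never used downstream.

## Problem sizes in the test suite

Cohort-level statistical properties (grade recovery, null calibration,
observer concordance) are scale-free, so the suite exercises them on a
96 × 96 px, 32-frame scene with every structure present, keeping runs
to seconds per cohort; geometry-bound checks — the kernel-size ordering
at the 45 px blush scale — run on the full 256 × 256, 60-frame default
scene with 10 patients per grade. Null calibration uses 20 master seeds
with a binomial-bound acceptance of the false-positive fraction at
most 0.25 around the nominal 0.05.

## Known limitations

* Scores depend on every option in `blush_options()`; the defaults
  reproduce one plausible reading of the native software, not a
  validated clinical instrument.
* The panning correction is integer-valued and global; it cannot
  represent rotation or local motion, which is precisely why ROI tracks
  exist in the workflow.
* Simulated absolute scores are not calibrated to any published score
  scale (no public angiograms exist to calibrate against).
* The rigid-motion simulator makes ground-truth tracking exact but
  understates how much real cardiac deformation corrupts a fixed ROI.
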