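---
title: "Methods: phantom-based hippocampal volumetry and ensemble classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based hippocampal volumetry and ensemble classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hippovol` implements a compact structural-MRI screening pipeline for early
Alzheimer's disease: threshold-based tissue volumetry, fixed-ROI hippocampal
area measurement, and a majority-voting ensemble of three classifiers. This
vignette records the model assumptions, the choices made where the procedure
left latitude, and what the synthetic phantom does and does not establish.

## Input model and assumptions

All image-level operations assume a **preprocessed** input: skull-stripped,
bias-corrected, motion-corrected, and spatially normalized so that fixed
pixel coordinates are anatomically comparable across subjects. Registration,
bias-field correction and brain extraction are deliberately out of scope —
they are mature external tools — and the package only contributes the
in-scope piece of preprocessing, motion correction by averaging repeat scans
(`average_scans()`), which reduces additive noise by `1/sqrt(k)`.
`read_slice()` ingests already-preprocessed NIfTI/Analyze volumes (with a
slice-axis/index selection), PNG or 16-bit TIFF slices.

The intensity model is the standard T1 ordering CSF < GM < WM, with the
brain mask given either explicitly, by the phantom, or implicitly as
"intensity exactly 0 is background" — the convention of brain-extracted
images.

## The GM threshold range

The three-way rule (`segment_tissues()`) classifies in-brain intensity
`f` against a range `[lo, hi]`: CSF strictly below `lo`, GM inclusively
inside, WM strictly above `hi`. A range compared with `<`, `==`, `>` is
only consistent under exactly this reading, so the boundary convention is
fixed and documented rather than configurable.

When no range is supplied, `estimate_thresh()` picks the two cut points
maximizing the between-class variance of a three-class partition of the
in-mask histogram (256 bins, exhaustive search over all cut pairs — a
three-class Otsu criterion). Exhaustive search over a 256-bin histogram is
cheap (~32k pairs) and deterministic; ties resolve to the first maximum in
scan order. Degenerate histograms (fewer than three distinct values) raise
an error advising a manual range. The threshold is estimated **per slice**
by default; `extract_features(thresh = "global")` estimates once and reuses
the range, and a fixed `thresh_range()` overrides estimation entirely —
whether a per-subject or global threshold is preferable on real data is an
open empirical question, so both are exposed.

## The hippocampus chain

For the normalized 498×498 coronal frame the left/right hippocampal ROI
rectangles are fixed at corners (130, 300)–(225, 360) and
(280, 300)–(375, 360). Coordinates are read as **(column, row), 0-based,
half-open**, which reproduces the published 95×60-pixel rectangles without
off-by-one ambiguity; since the source states only corner pairs, this
convention is a package decision, it is documented on `roi_rect()`, and
custom masks can be passed to override it. For other frame sizes the
rectangles scale proportionally with half-up rounding (`floor(x + 0.5)`),
so that e.g. a half-size frame maps corner 225 to 113.

The per-side chain is:

1. **ROI extraction** — a plain sub-image copy.
2. **Noise removal** (`remove_noise()`) — binarize at `lo` (tissue versus
   CSF/background; the source procedure names "the binary image" without
   defining the cut, and `lo` is the only threshold in play), open with a
   disc of radius 1 (configurable; no structuring element is prescribed
   anywhere, and radius 1 removes single-pixel specks while preserving
   hippocampal-scale bodies), then keep the **largest 8-connected
   component**, with ties broken by the smallest top-left bounding-box
   corner for determinism. EBImage performs the opening; the 8-connected
   labelling is implemented in-package because the installed labeller is
   4-connected.
3. **Region trimming** (`trim_region()`) — crop to the component's bounding
   box expanded by a 2-pixel margin (clipped at the ROI border) and
   suppress non-component pixels to 0. "Cut down the border regions" names
   no operator; a padded bounding-box crop with component masking is the
   minimal concretization that provably never removes component pixels.
4. **Hippocampus separation** (`extract_hippocampus()`) — within the
   retained component, keep pixels in the GM range `[lo, hi]`. The
   hippocampus is a GM structure in a CSF pool, so "high intensity
   values" relative to their CSF surroundings are precisely GM-range
   intensities; no second threshold is introduced.
5. **Area** — the count of mask pixels, on a single slice per subject
   (coronal slices are perpendicular to the hippocampal long axis). A
   multi-slice summation can be had by summing per-slice results; the
   single-slice default reflects that no slice-selection rule is
   recoverable, so slice choice is left to the caller's configuration.

Any stage that produces an empty mask yields area 0 with a warning rather
than an error: a failed extraction is a data point, not a crash.

On a noiseless phantom the chain recovers the painted ellipse **exactly**
at full frame size; the radius-1 opening can shave single boundary pixels
off very small structures (noticeably below ~10 px semi-axes, e.g. on
strongly downscaled frames), which is the expected cost of speck removal.

## The classifier ensemble

The feature vector is (vol_gm, vol_wm, vol_csf, left_area, right_area);
eight standard subsets of it are addressable by name (`feature_subsets()`).
Labels are +1 (AD) and −1 (control). The ensemble decision is the literal
majority rule: +1 iff the +1 votes strictly exceed n/2, so even-n ties
resolve to control — the conservative direction for a screening tool.

* **SVM** — `e1071::svm`, RBF kernel; `C ∈ {0.1, 1, 10, 100}`,
  `γ ∈ {0.001, 0.01, 0.1, 1}` tuned by stratified 3-fold inner CV *within
  the training folds* (nested tuning; tuning on the outer test fold would
  leak). Only "optimized by cross validation" is prescribed; the grids are
  conventional decade grids.
* **MLP** — two hidden layers of three sigmoid neurons, online
  backpropagation with learning rate 0.3 (prescribed), momentum 0.2 and at
  most 500 epochs (the customary defaults of the WEKA-style implementation
  this architecture mimics), seeded uniform [−0.5, 0.5] initialization,
  fixed visiting order. No installed R package fits a two-hidden-layer
  perceptron, so the package carries its own (~60 lines). Training stops
  early when the epoch MSE drops below 10⁻³ or has not improved for 50
  epochs — a numerical convergence guard, not a model change.
* **Decision tree** — `rpart` with entropy ("information") splits,
  `minsplit = 4`, `minbucket = 2`, no surrogate splits. C4.5's pessimistic
  pruning at confidence 0.25 has no exact installed equivalent; the
  confidence factor maps monotonically onto rpart's complexity penalty,
  `cp = 0.01 · 0.25 / conf`, anchoring each tool's standard pruning
  strength to the other's (both 0.25 and cp = 0.01 are their respective
  defaults). The contract preserved is "a pruned univariate decision
  tree".

Features are z-scored with training-fold statistics by default (an RBF
kernel on raw pixel-count scales is degenerate). Cross-validation
(`crossvalidate()`) uses stratified folds from a documented seed, trains
per fold, and **pools** test-fold predictions into one confusion matrix per
classifier (micro-averaging); per-fold macro-averaging is the main
alternative, but pooling keeps the counts interpretable at modest n.
Metrics are accuracy, specificity (true-negative rate on controls) and
sensitivity (detection rate on AD), in percent, with a zero denominator
reported as `NA` rather than an arbitrary number. Reports are tidy-friendly:
`tidy()` (per-classifier), `glance()` (ensemble row), `autoplot()` (metric
bars).

## The phantom

The generator exists so that every downstream stage has a ground truth. A
`phantom_spec()` paints, on a `width × height` grid (default 498×498):

* background 0 outside a brain disc (radius 230 px at full frame);
* a CSF rim (12 px), a GM annulus (30 px) and a WM interior, at mean
  intensities 60 / 110 / 170 on a 0–255 scale — the T1 ordering with
  comfortable margins for thresholding;
* inside each hippocampal ROI rectangle, a CSF-filled pool containing a
  GM-intensity ellipse (semi-axes 20×12 px) — the minimal geometry under
  which "binarize, open, keep the largest object" isolates the
  hippocampal body, since the pool disconnects it from the WM surround;
* optional additive Gaussian noise (sd in gray levels) inside the brain,
  clamped to stay positive so the background-0 convention survives noise;
* an optional multiplicative bias field `1 + a·cos(2πx/w)·cos(2πy/h)`,
  a smooth low-frequency stand-in for scanner shading.

**Atrophy** `a ∈ [0, 1)` scales the hippocampal semi-axes and the GM
annulus thickness by `(1 − a)`, with the freed annulus space becoming CSF
at fixed brain radius — so GM falls, CSF rises and hippocampal area shrinks
by `(1 − a)²`, the qualitative direction of AD. Cohorts
(`generate_cohort()`) draw per-subject atrophy from truncated normals
(defaults: AD mean 0.3, control mean 0.05, sd 0.05 — a deliberately strong,
cleanly separable effect) and derive per-subject seeds from the cohort
seed, making whole cohorts pure functions of their specification.
`generate_feature_table()` bypasses imaging entirely with class-conditional
Gaussian features, for isolating the classification layer (chance behaviour
under identical means; near-perfect accuracy under wide separation).

**What the phantom does not emulate:** real anatomy (no gyri, no partial
volume, no texture), registration error, heteroscedastic or Rician MRI
noise, skull/scalp, 3D continuity, and inter-subject anatomical
variability beyond the atrophy factor. Consequently, passing tests show
that the operators are implemented correctly and respond to controlled
effects in the right direction and magnitude — they do **not** certify
clinical accuracy, and the near-perfect synthetic classification results
must not be read as expected performance on real cohorts.

## Determinism and problem sizes

Every stochastic component — phantom noise, atrophy draws, fold
assignment, inner tuning folds, MLP initialization — is derived from
explicit integer seeds, and repeated runs are bit-identical (the test suite
checks artifact files by checksum). The test and acceptance workloads use
full-size 498×498 phantoms where exactness is asserted, a one-third-scale
frame (166×166) for routine unit tests, a 37 + 48 subject cohort for the
end-to-end discrimination check (mirroring a typical single-site study
size) and a 200-subject null table for the chance-level check; these sizes
were chosen as the smallest that make the statistical assertions sharp.

## Known limitations

* The fixed-ROI approach presumes accurate spatial normalization; on
  poorly registered data the rectangles will miss the hippocampus, and the
  package deliberately does not attempt deformable segmentation.
* The GM-range separation inherits any threshold-estimation bias; strong
  uncorrected bias fields will degrade both volumetry and area measurement
  (the phantom's bias amplitude lets you quantify this).
* The tree's pruning-strength mapping is an analogue, not a reimplementation
  of C4.5's pessimistic pruning; trees may differ from J48's on the same
  data even though both are pruned univariate trees.
* Single-slice areas are sensitive to slice selection, which is left to the
  caller; volumetric (multi-slice) summation is available but not default.
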