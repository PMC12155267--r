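---
title: "Measuring thoracic kyphosis from sagittal silhouettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring thoracic kyphosis from sagittal silhouettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kyphoscan)
```

## The measurement model

Clinically, thoracic kyphosis is quantified by molding a flexible ruler
(flexicurve) to the back between the T1 and T12 vertebrae, tracing it onto
millimetric paper, and reading off the chord length $L$ between the
endpoints and the maximum depth $d$ of the curve from the chord. Treating
the traced curve as a circular arc, the subtended angle is

$$\theta \;=\; 2\,\arcsin\!\frac{4dL}{4d^2+L^2},$$

which on the physiological branch ($0 \le d < L/2$) is equivalent to
$\theta = 4\arctan(2d/L)$ — an identity the test suite confirms to
$10^{-9}$ degrees over a $10^4$-point grid, and which yields the exact
inverse $d = (L/2)\tan(\theta/4)$ used by the synthetic generator. The
formula depends only on $d/L$, so any consistent length unit works;
`kyphoscan` operates in pixels and never needs a camera calibration.

`kyphoscan` automates the reading from a sagittal photograph of a standing
subject:

1. **Segmentation** produces a binary person mask.
2. **Landmark localization** places the T1 and T12 rows at calibrated
   fractions $r_1$ and $r_1 + r_2$ of body height below the head-top row,
   where $(r_1, r_2, r_3)$ are the head-to-T1, T1-to-T12 and T12-to-foot
   fractions averaged over an annotated training cohort. The fractions
   telescope to 1 by construction.
3. **Dorsal contour extraction** takes the rearmost mask column of each
   row between T1 and T12, and the chord/sagitta of that contour feed the
   arc formula.

### Assumptions

* The subject stands upright in profile, fully inside the frame, with the
  back (dorsal side) toward one image edge; head-top and foot-bottom rows
  of the mask are the true body extremes (hair, hats and footwear bias
  the height estimate and hence the landmark rows).
* Body proportions of the measured subject resemble the calibration
  cohort: the ratios are population averages, not per-subject anatomy.
* The thoracic back contour is reasonably approximated by a single
  circular arc. No spline or multi-segment fitting is attempted; a
  double-curved (kypho-lordotic) contour is summarized only by its
  maximal deviation from the T1–T12 chord.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `ratios` | `locate_landmarks()` | calibrated | body-height fractions (dimensionless); defaults for synthesis are (0.12, 0.28, 0.60) |
| `facing` | `locate_landmarks()` | `"auto"` | which image side is the back; `auto` picks the T1–T12 edge with the larger outward bow |
| `smooth` | `dorsal_contour()` | 5 rows | odd running-median window on the contour; robust to single-row mask noise without flattening the arc apex |
| `border_px` | `segment_threshold()` | 5 px | image-border width for the background color model |
| `threshold` | `segment_threshold()` | Otsu | fixed cut on the color-distance map, if preferred over Otsu |
| `tol` | `boundary_f1()` | 0.75% of image diagonal, rounded up | boundary-matching distance tolerance in pixels |
| `form` | `icc()` | `"agreement"` | ICC form; see below |

## Design choices

**Coordinate convention.** All landmark arithmetic uses y increasing
upward, so body height is `y_head - y_foot` and the ratio formulas read
naturally; `row_to_y()`/`y_to_row()` adapt image row indices. Landmark
rows are rounded to the nearest grid row with ties toward the head —
deterministic, and immaterial at working resolutions.

**Depth as maximal deviation.** `d` is the *maximum* perpendicular
distance from the contour to the chord, not the deviation at the chord
midpoint. The two coincide exactly for a circular arc; on real contours
the maximum is the more robust reading of "depth of the curve" and is the
convention used here throughout.

**Dorsal side resolution.** Acquisition protocols fix the subject's
orientation, so `facing` can be set explicitly; the `auto` heuristic
compares the outward bow of the left and right T1–T12 edges and picks the
larger, which is correct whenever the thoracic back is convex outward —
its failure mode (severely concave backs) is outside the instrument's
intended population. Ties (perfectly flat backs) resolve to the left edge,
where the measured angle is 0 either way.

**Segmentation backend.** The deployed system this package models uses a
trained convolutional network for segmentation; training such a model is
neither desk-scale nor possible without the clinical images, so the
package defines segmentation as a pluggable contract and ships a
deterministic reference backend: background color estimated as the
per-channel median of a 5-px image border, per-pixel Euclidean color
distance, Otsu binarization, then cleanup (largest 8-connected component,
interior holes filled). On scenes with an approximately uniform or
smoothly varying background — the acquisition protocol the instrument
assumes — this backend exceeds 0.99 global accuracy; a learned backend
can be dropped in via `register_backend()` without touching the rest of
the pipeline.

**Metric conventions.** Weighted IoU uses ground-truth class-frequency
weights (the toolbox convention). Empty-union IoU is defined as 1 (both
masks agree the class is absent). Boundary pixels are class pixels
4-adjacent to another class, with the image frame counting as a class
change; the BF-score tolerance defaults to 0.75% of the image diagonal.
These conventions are stated because the metric definitions leave them
open; all are configurable.

**ICC form.** The default is the two-way random, absolute-agreement,
single-measurement form ICC(A,1), the usual choice for method-comparison
studies because it penalizes systematic offsets between methods; the
consistency form ICC(C,1) is available via `form = "consistency"`.
Confidence bounds use the standard F-distribution constructions
(Satterthwaite degrees of freedom for the agreement form). The SD is the
sample (n−1) form. Spearman p-values use the t approximation by default,
with the exact small-sample distribution available.

## The synthetic generator

`generate_subject()` rasterizes an upright silhouette — head disc, neck,
torso, leg block — whose dorsal edge between the T1 and T12 rows is a
circular arc with chord $L = r_2 H$ and sagitta $d = (L/2)\tan(\theta/4)$,
so the prescribed angle is exact by construction (any non-arc dorsal curve
would make "true $\theta$" ill-defined under the arc model). Ground-truth
landmarks keep exact sub-pixel T1/T12 positions; the mask itself is
rasterized to whole pixels. Optional boundary-pixel noise flips a fraction
of edge pixels; `render_scene()` composites the silhouette over uniform,
gradient or textured backgrounds with additive Gaussian noise, emulating
background-modification data augmentation (several scenes, one shared
ground-truth mask). Cohorts draw angles from a truncated normal —
defaults Normal(32°, 10°) truncated to a physiological range, matching
the young-adult population the instrument targets — with per-subject
seeds derived from the cohort seed by counter offset.

What the generator does *not* emulate: clothing folds, hair, perspective
and lens distortion, depth cues, pose variation, and cluttered real-world
backgrounds. Passing the recovery tests therefore demonstrates that the
geometry, landmark and statistics stages are correct and that the
pipeline is internally consistent — not that the reference segmentation
backend would survive field photographs; that is what the backend
contract and a trained model are for.

## Numerical behavior and degenerate inputs

* Rasterization limits accuracy: the arc sagitta is realized in whole
  pixels, so a single measurement carries up to ~0.5 px depth error —
  about 1° at an 800-px body height (224-px chord). The recovery suite
  runs 50 subjects at that height (a few seconds of compute) and observes
  mean absolute error ≈ 0.5° and max < 1°; taller images reduce the error
  proportionally.
* `d ≥ L/2` is rejected, not clamped: it breaks the arcsin branch and is
  anatomically meaningless. Perpendicular distances below $10^{-9}$ are
  treated as collinear (depth 0, angle 0).
* Degenerate inputs raise stage-named errors rather than propagating NaN:
  empty masks, silhouettes with a broken row between T1 and T12,
  coincident chord endpoints, zero body height, constant columns in the
  rank correlation, zero between-subject variance in the ICC.
* A batch (`measure_batch()`) records per-subject failures as warnings
  and continues; measurement on a supplied mask is fully deterministic.

## Known limitations

* The proportion ratios are cohort averages; atypical body proportions
  shift the T1/T12 rows and bias the angle. Calibration on a matched
  cohort is essential.
* The single-arc model underestimates complex curvatures; only the
  maximal chord deviation is reported.
* The reference segmentation backend assumes a contrasting, roughly
  uniform background and will fail on cluttered scenes; it is a contract
  reference implementation, not a general person segmenter.
* Angles are reported to 3 decimal places in CSV output; the underlying
  precision is limited by rasterization as described above.
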