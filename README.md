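# kyphoscan

Automated measurement of the thoracic kyphosis angle from sagittal-view
images of standing subjects.

Thoracic kyphosis — the natural anterior-concave curvature of the spine
between vertebrae T1 and T12 — is normally 20–40° in young adults. The
radiographic gold standard (Cobb angle) is accurate but costly and exposes
the patient to radiation; the common clinical alternative, the flexicurve
ruler, is cheap but slow (~15 min per subject) and operator-dependent.
`kyphoscan` implements a camera-based alternative for clinicians and
posture researchers: it measures the angle automatically from a plain
side-view photograph, with no radiation and no special clothing or
markers.

## Method

The pipeline mirrors how an expert reads a flexicurve tracing:

1. **Segmentation.** The person silhouette is extracted from the RGB image
   as a binary mask. The segmentation stage is a pluggable backend
   contract; the package ships a deterministic border-color threshold
   backend (background color modeled from the image border, per-pixel
   color distance binarized by Otsu's method), and a learned model can be
   registered under the same contract.
2. **Landmark localization.** The T1 and T12 rows are placed at calibrated
   fractions of body height. On annotated training subjects with landmark
   points P1 (head top), P2 (T1), P3 (T12), P4 (foot bottom), the ratios

   r1 = (y1 − y2)/H,  r2 = (y2 − y3)/H,  r3 = (y3 − y4)/H,  H = y1 − y4

   are averaged over the cohort; on a new silhouette the head and foot
   rows come from the mask extremes and T1/T12 follow from the ratios.
3. **Dorsal contour and chord geometry.** The rearmost silhouette column
   of each row between T1 and T12 forms the back contour. Its chord length
   L (T1–T12 distance) and sagitta d (maximum perpendicular deviation from
   the chord) feed the flexicurve arc formula

   θ = 2·arcsin( 4dL / (4d² + L²) )   (degrees)

   which is scale invariant (depends only on d/L), so pixel units suffice.
4. **Validation.** Agreement between the automated angle and a reference
   method is summarized by Spearman's ρ, the intraclass correlation
   coefficient ICC with 95% CI, and Cronbach's α.

A synthetic-silhouette generator produces masks whose dorsal edge is a
circular arc of prescribed angle with exact landmark ground truth, so the
entire pipeline is testable without clinical images.

## Worked example

```r
library(kyphoscan)

# flexicurve tracing of a clinical subject: chord 32 cm, depth 2.1 cm
kyphosis_angle(L = 32, d = 2.1)
#> [1] 29.90932

# synthetic subject with a prescribed 30-degree kyphosis
s <- generate_subject(synth_spec(theta = 30, seed = 42))
s
#> Synthetic subject: 900 x 520 mask, height 800 px, theta 30.00 deg (L = 224, d = 14.75 px)

measure_kyphosis(s$mask, s$ratios, subject_id = "S001")
#> Kyphosis measurement [S001]: theta = 30.513 deg (L = 224.0 px, d = 15.00 px, back: right)
```

The 0.5° discrepancy is rasterization error: the true sagitta 14.75 px can
only be realized as whole-pixel columns in the mask. On a 50-subject
synthetic cohort with 2% boundary-pixel noise:

```r
co   <- generate_cohort(50, theta_range = c(18, 50), seed = 42, noise_rate = 0.02)
recs <- measure_batch(lapply(co$subjects, `[[`, "mask"), c(0.12, 0.28, 0.60))
ref  <- data.frame(subject_id = co$manifest$subject_id,
                   actual_angle_deg = co$manifest$true_theta_deg)
validate_measurements(recs, ref)
#> Method-agreement reliability (n = 50 subjects)
#>   Spearman rho    0.995  (p = 4.77e-49)
#>   ICC [agreement]  0.997  (95% CI 0.995-0.998)
#>   Cronbach alpha  0.999
#>   reference  33.59 +/- 7.43 deg
#>   predicted  33.56 +/- 7.35 deg
```

ρ, ICC and α near 1 mean the recovered angles track the prescribed ones
almost perfectly; on real photographs the segmentation stage, clothing and
posture variation add error that these synthetic scenes do not model (see
the methods vignette).

A command-line wrapper with `simulate`, `calibrate`, `segment`, `measure`,
`evaluate` and `stats` subcommands is installed at
`inst/cli/kyphoscan.R`:

```sh
Rscript inst/cli/kyphoscan.R simulate --n 10 --out-dir scenes --seed 1
Rscript inst/cli/kyphoscan.R segment --image scenes/S001_scene.png --out-mask pred.png
Rscript inst/cli/kyphoscan.R evaluate --pred pred.png --gt scenes/S001_mask.png
```

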