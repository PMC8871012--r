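---
title: "Measuring the Cobb angle from vertebral corner landmarks"
author: "cobbangle authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the Cobb angle from vertebral corner landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobbangle)
```

## The measurement problem

The Cobb angle is the clinical standard for grading scoliosis severity on
an anterior-posterior spine radiograph: the angle between the superior
endplate of the most tilted vertebra above the curve apex and the inferior
endplate of the most tilted vertebra below it. Manual measurement with
film and protractor — and even semi-automatic measurement where a clinician
clicks endplate lines in a PACS viewer — carries inter- and intra-observer
variation of several degrees, enough to matter at bracing and surgical
decision thresholds.

`cobbangle` automates the geometric half of this problem. Its input is a
set of vertebral corner landmarks: up to 17 thoracic and lumbar vertebrae,
each located by its four box corners in pixel coordinates, each carrying a
detection score in [0, 1]. Such landmarks typically come from a keypoint
detection network; this package deliberately treats the detector as an
exchangeable upstream component and consumes its output from files (or
from the built-in phantom generator), so the measurement pipeline can be
specified, tested and audited in isolation.

## The pipeline

`measure_cobb()` runs five stages:

1. **Score filtering.** Boxes with detection score strictly above 0.5
   (configurable) are retained. Fewer than five usable vertebrae abort the
   measurement with an explicit infeasibility error — a Cobb angle from
   four boxes would be clinically meaningless.
2. **Lateral outlier rejection.** Adjacent vertebrae cannot be far apart
   laterally. A box whose x-center deviates from the mean x-center of its
   nearest usable neighbours above and below by more than half its own
   width is rejected. Two refinements proved necessary in practice:
   rejection is *greedy and iterative* (flag the worst offender, recompute
   all references from the remaining boxes, repeat), because a single
   grossly displaced box otherwise contaminates the references of its
   well-placed neighbours and drags them into rejection; and an *end* box,
   which has neighbours on one side only, is compared against the linear
   extrapolation from the two nearest boxes on that side rather than
   against its single neighbour's x-center. The latter matters for steep
   curves: near 80 degrees the lateral step between healthy neighbouring
   vertebrae exceeds half a box width, so a raw single-neighbour
   comparison would reject healthy end vertebrae — the extrapolated
   reference cancels the slope and responds only to genuine displacement.
3. **Curve-fit imputation.** Up to two rejected boxes are rebuilt: center
   x comes from a least-squares cubic of center x on center y fitted over
   the 8 nearest good boxes (a windowed fit; a single global cubic leaves
   a residual of about 2.4% of the arch amplitude on a half-sine arch,
   more than a pixel at realistic amplitudes), and width, height and
   endplate tilt are linearly interpolated in y from the good boxes.
   Rebuilt boxes keep their original center y and are flagged `imputed`.
   With fewer than four usable points the fit degrades to linear and says
   so. More than two bad boxes abort the measurement rather than invent a
   spine.
4. **Apex detection.** The apex is operationalized as the box center with
   the maximum perpendicular distance from the chord joining the first and
   last centers — the most laterally placed vertebra relative to the
   spine's own endpoints, which makes the choice invariant to in-plane
   rotation of the radiograph. Ties break toward the superior candidate.
   The left/right *gap profile* (distances between facing corner pairs of
   adjacent boxes) determines convexity: gaps open on the convex side, so
   the side with the larger summed profile names the curve direction. If
   every center sits within 1 px of the chord the spine is treated as
   straight: angle 0, apex at the middle box, flagged `zero_curve`.
5. **End-vertebra selection and the angle.** The superior end vertebra
   maximizes the absolute top-edge tilt over boxes at or above the apex;
   the inferior end maximizes the absolute bottom-edge tilt at or below
   it. The apex is eligible on both sides (so the candidate set is never
   empty when the apex falls at an end), and ties break away from the
   apex, mirroring how a clinician reaches outward for the last clearly
   tilted vertebra. The Cobb angle is
   `|tilt_top(superior) - tilt_bottom(inferior)|`, the intersection angle
   of the two endplate lines.

### Conventions

All coordinates are image pixels, origin top-left, x rightward, y
downward; vertebrae are ordered superior to inferior and indices are
1-based, as everywhere in R. Edge tilt is measured from the left corner to
the right corner and folded into (-90, 90] degrees; with y growing
downward, a positive tilt is clockwise on screen. Angles are kept as
floating point internally; reports also carry the nearest integer, rounded
half away from zero, since clinical tables quote integer degrees.

## The phantom generator

`generate_phantom()` produces spines with analytically known ground truth,
so every pipeline stage is testable without patient data. The centerline
is a single arch, `x(y) = x0 + A sin(pi (y - y0) / L)`, straight outside
it — a deliberate emulation of a single major scoliotic curve. Vertebra
centers are equally spaced in y across the arch; each box's endplates are
perpendicular to the local centerline tangent, so the tangent angle
`theta(y) = atan(dx/dy)` transfers directly to endplate tilt and the
phantom's true Cobb angle is the range of `theta` over the vertebra
centers (`true_cobb()`). `amplitude_for_cobb()` inverts this relation by
bisection to 0.1 degrees, since the angle is strictly increasing in `A`.

Defaults describe a plausible digital radiograph: a 512 x 1024 px image,
17 vertebrae, widths tapering 64 to 96 px toward the lumbar spine, 32 px
heights, detection scores uniform on [0.85, 1], and i.i.d. Gaussian corner
jitter with sigma = 1 px as a minimal stand-in for landmark-detection
error. What the phantom does *not* emulate is equally important: no ribs,
pelvis or radiographic texture, no double curves, no correlated or
heavy-tailed detection failures, no score-error dependence. Passing tests
on phantoms therefore validate the geometry and its error handling, not
detector robustness on clinical images.

`render_image()` rasterizes a phantom as bright vertebra quadrilaterals on
a torso-shaped mid-gray band over a darker surround with additive Gaussian
noise — just enough structure to exercise the texture features and window
classifiers of the cropping stage.

## The cropping stage

Radiographs arrive at widely varying sizes with collimation borders and
annotations; the cropping stage standardizes them to the torso before any
landmark work. Texture is summarized by local binary patterns: each pixel
is coded by thresholding its eight radius-1 neighbours against the center
(`g(z) = 1` for `z >= 0`, ties counting as 1 — a uniform patch codes to
255) and packing the bits clockwise from the top-left neighbour. The code
depends only on the *sign* of gray-level differences, so it is invariant
to monotone intensity changes — the right property for radiographs of
wildly varying exposure. Windows are described by the L1-normalized
256-bin histogram of their interior codes; border pixels are skipped
rather than padded, to avoid fabricating intensities.

Classification is discrete AdaBoost over decision stumps on single
histogram bins: per round, the stump minimizing weighted error is chosen,
`beta = eps / (1 - eps)` (with `eps` clamped to `[1e-10, 0.5 - 1e-10]`),
correctly classified samples are down-weighted by `beta`, and the strong
decision is the weighted-majority vote with weights `log(1/beta)` — the
window is positive when the voting weight reaches half the total. Stages
of such classifiers form a rejection cascade (default 3 stages), each
later stage trained on the survivors of the earlier ones. The sliding
window scans row-major, coarse to fine scale, and `crop_body()` returns
the union box of all positive windows. The number of stages, window
sizes, strides and negative-sampling scheme are configuration, not claims:
no attempt is made to reproduce any particular trained detector.

## Detector support math

Three pieces of keypoint-detector mathematics are implemented exactly and
tested against brute-force evaluation: the penalized focal loss over
heatmap cells (positives contribute `(1-p)^2 log p`, negatives
`(1-t)^4 p^2 log(1-p)`, averaged and negated; predictions clamped to
`[1e-7, 1 - 1e-7]`), the mean Euclidean landmark error, and the
encode/decode pair for center/corner offset maps. Encoding splats a
Gaussian (sigma = 2 grid cells) around each downsampled center with an
exact 1 at the peak cell and stores sub-cell center offsets and per-corner
displacements at the peak; decoding takes the top-k heatmap peaks under
3x3 non-maximum suppression (a cell survives when no neighbour exceeds
it) and inverts the arithmetic. The round trip is exact by construction —
the quantization lost to the stride is exactly restored by the stored
offsets — which pins the coordinate bookkeeping that detector plumbing
usually gets subtly wrong. The feature-map stride is a free parameter
(default 4).

## The observer-agreement suite

The evaluation module reproduces a published 70-image agreement study
packaged as `inst/extdata/tables_1_4.csv`: for each image, the Cobb angle
measured by a scoliosis specialist (Observer 1, the reference), a second
clinician (Observer 2), and the automated method, with the severity
stratum (<10, 10-25, >25-40, >40 degrees). Only raw angles are stored —
accuracies, differences and within-tolerance flags are always recomputed —
and `load_fixture_records()` refuses to return anything that fails its
row-count, stratum-count and column-checksum validation.

Percentage accuracy is `100 - 100 |ref - test| / ref`, deliberately
unclipped. Summaries report medians and interquartile ranges with
quartiles by linear interpolation between order statistics, and the count
of measurements within ±5 degrees, the band conventionally accepted in
clinical Cobb measurement. Group comparisons use the two-sided
Mann-Whitney U test (normal approximation, tie correction, no continuity
correction) and the chi-square test without Yates correction.

Reliability offers both faces of the two-way random-effects,
absolute-agreement intraclass correlation: single measures ICC(2,1) — the
defensible default when the question is "how reliable is one rating" —
and average measures ICC(2,k). On this fixture the single/average forms
give 0.991/0.995 (Observer 1 vs automated), and the published reliability
figures coincide with the average-measures form; `reliability_table()`
reports both so the reader need not guess which convention a source used.

One data note: the source table's *printed* accuracy cells for one mild
image (reference 5, ratings 3 and 6) are inconsistent with the accuracy
formula applied to its printed raw angles, and the printed medians of the
mildest stratum inherit that inconsistency. This package recomputes
everything from the raw angles; the headline statistics (overall and
severe-stratum medians, within-±5° counts, correlations) are insensitive
to the affected row.

## Numerical choices and test scale

Collinearity below 1 px of chord deviation counts as a straight spine;
probability clamps are 1e-7 (focal loss) and [1e-10, 0.5 - 1e-10]
(AdaBoost error); NMS ties keep all tied peaks and rank them by value,
then row-major position; quartiles use linear interpolation (R type 7).
The test suite measures roughly 250 phantoms end to end (200 noisy ones
for parameter recovery — mean absolute error must stay within 3 degrees
at 1 px corner noise, within 1 degree noise-free — plus 100 for
apex/end-selection cross-checks against exhaustive search and assorted
invariance cases), trains small boosted cascades on generated scenes, and
completes in well under a minute; the sizes were chosen to exercise every
code path at tight tolerances, and all randomness is seeded.

## Known limitations

Only a single major curve is measured; double and minor curves — which can
be clinically relevant — are out of scope, as is naming vertebral levels
(T1-L5) or any sagittal-plane angle. Rotation invariance of the measured
angle holds for in-plane rotations smaller than half the per-side tilt
range; beyond that the most-tilted-vertebra selection legitimately
changes, because the Cobb definition itself references the film's
horizontal. The cropping stage is a generic textured-window detector:
it demonstrates the LBP/boosting machinery on synthetic scenes and makes
no claim of clinical-grade torso localization. And the observer-agreement
statistics quantify agreement with one expert on one 70-image set — they
are reproducible summaries of that study, not evidence of performance on
other populations or imaging chains.
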