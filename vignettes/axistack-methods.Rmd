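---
title: "axistack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{axistack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(axistack)
```

## The problem

Within the first minutes of a cardiovascular MR study, a stack of thick
transaxial bright-blood "anatomy" slices is acquired for planning. These
slices are not heart-aligned and are coarse through-plane, but they cover
the whole thorax. axistack implements an automated triage pipeline over
such stacks: segment each slice into nine anatomical classes, reassemble
the stack into a 3D thorax model by trilinear interpolation, derive
body-surface-area (BSA) indexed chamber volumes, LV mass, ascending
aortic diameter and pleural fluid volume, and classify the study against
published abnormality cut-offs. Because no patient data ship with the
package, a synthetic thorax phantom generator with analytically known
structure volumes makes every stage testable end to end.

## Label vocabulary and geometry conventions

Nine classes (ids 0–8): background, aorta, left atrium, LV wall, LV
cavity, pulmonary artery, pleural effusion, right atrium, RV cavity. The
aorta is a single class — ascending and descending segments are separated
geometrically later — and pericardial effusion is not part of the
vocabulary.

Pixel indices are 0-based; the world position of a pixel or voxel center
is `(index + 0.5) * spacing` in-plane and `slicePosition` through-plane.
Center-of-voxel sampling keeps the trilinear interpolation symmetric.
Slices are kept sorted by ascending through-plane position; that order
defines the z axis, and none of the derived measures depend on the stack
direction. Image matrices run anterior→posterior down the rows —
"anterior" for the ascending-aorta rule means small row indices.

## The phantom generator

A phantom is a list of solid primitives painted into an isotropic voxel
grid in order (painter's algorithm): ellipsoids for chambers, an
ellipsoid shell for the LV wall, vertical tubes for the great vessels,
and a posterior crescent prism (a lune between two offset equal circles,
extruded in z) for pleural effusion, whose circle offset is solved
numerically so its analytic volume equals the requested millilitres
exactly. Truth volumes are the closed forms (ellipsoid 4/3·π·abc, shell
outer − inner, cylinder π·r²·h); any class that gains or loses voxels to
a later overlapping primitive has its truth recomputed voxel-exactly at
build resolution so recovery tests remain fair under overlap.

Slicing mimics thick-slab acquisition: each emitted slice's label map is
the slab-overlap-weighted majority class per pixel column (not
center-sampling), reproducing the partial-volume flavour of real anatomy
stacks; the slice count is `floor((zExtent − t)/(t + g)) + 1` for
thickness t and gap g. Rendering assigns each class a mean intensity
(defaults at least 40 units apart, bright blood pools, darker myocardium
and fluid) plus i.i.d. Gaussian noise (default SD 5), rounded to the
16-bit integer range. All randomness flows through explicit seeds via a
private RNG stream; the caller's `.Random.seed` is untouched.

Six presets ship, one per diagnostic flag plus a normal study, each sized
at least 15% beyond its cut-off at BSA 1.9 m²: `normal`, `dilated_lv`
(LVEDVi ≈ 108.6), `hypertrophied_lv` (LVMi ≈ 96.6), `raised_mvr`
(MVR ≈ 0.97), `dilated_aorta` (indexed diameter ≈ 21.1), and
`pleural_effusion` (150 ml). One coupling is arithmetic, not a modelling
choice: LVMi > 83.5 with LVEDVi ≤ 94 forces MVR ≥ 83.5/94 ≈ 0.888 >
0.84, so the hypertrophied preset necessarily raises the raised-MVR flag
too; its expected flag set is therefore both, and a separate `raised_mvr`
preset isolates that flag.

What the phantom does *not* emulate: MR physics (coil shading, banding),
cardiac motion, breathing artefact, oblique acquisitions, or the texture
statistics of real tissue. Tests passing on phantoms demonstrate the
geometry, interpolation, calibration and statistics of the pipeline —
not segmentation performance on clinical images.

Default slice thickness/gap for emitted phantom stacks are 8 mm / 2 mm —
a configurable guess typical of anatomy localizers; the acquisition
protocols behind the published cut-offs do not pin these down.

## Segmentation

`preprocessCanvas` reproduces the published preprocessing contract:
aspect-preserving resample of the longer side to 560 pixels with the
shorter side centered in zero padding; `postprocessCanvas` inverts it
exactly for integer-ratio scales (nearest-neighbour both ways, so label
maps never acquire invented classes).

Three `Segmenter` implementations share one generic:

* **OracleSegmenter** returns held ground truth, optionally corrupting
  exactly `floor(rate · nPixels)` pixels per slice to uniformly random
  *different* classes under a per-slice derived seed. It decouples
  downstream validation from segmentation quality.
* **NearestMeanSegmenter** classifies each pixel to the nearest class
  mean intensity (ties to the lowest id); on a noise-free rendering it
  inverts the renderer exactly.
* **TrainableSegmenter** is a deliberately small per-pixel multinomial
  softmax classifier over a radial-basis expansion of intensity (11
  Gaussian bumps spanning the intensity range, width 25) plus normalized
  row/column coordinates — about 135 parameters. A full convolutional
  encoder–decoder would be the natural choice at clinical scale; for
  desk-scale phantom imagery the class-conditional intensity structure
  carries nearly all the signal, and the Segmenter contract keeps any
  stronger model drop-in. The RBF block carries a gain of 40 so that the
  optimal softmax weights are small in magnitude: Adam's per-parameter
  steps are bounded by the learning rate, so at the recipe's 0.001 the
  optimum must sit within a few hundred steps of the origin to be
  reachable quickly. This is a feature-scaling choice, not a change to
  the optimizer.

Training follows the published recipe: categorical cross-entropy over
batches of 20 images, learning rate 0.001 (plain Adam; fancier
rectified/lookahead variants are not reimplemented), random rescale
(0.9–1.1), rotation (±10°), shear (±5°) and translation (±5%)
augmentation applied jointly to image and label map, and stopping when
the validation loss plateaus. "Plateau" is defined as no new validation
minimum for `patience` (default 5) consecutive epochs; the weights at
the lowest validation loss are returned. Each image contributes a random
subsample of 1500 pixels per step rather than the full frame — the model
is a pixel classifier, so this is plain stochastic minibatching.
Everything is reproducible under the config seed. Per-pixel argmax over
the nine class scores decides the label, ties to the lowest class id.

The trainable segmenter operates at the native slice resolution: its
features are resolution-independent, so the 560×560 canvas adds cost but
no information for it. The canvas ops remain the documented entry point
for models that need a fixed input shape.

## Reconstruction

`assembleVolume` one-hot encodes each slice's label map per class,
resamples in-plane bilinearly onto a common grid (finest pixel spacing in
the series; differing extents resample onto the union bounding box), and
interpolates the per-class indicator fields linearly along z — trilinear
interpolation of occupancy, not argmax relabeling, preserving
partial-volume information for volumetry. The through-plane target
spacing is `min(2 mm, finest in-plane spacing)`. Whether to interpolate
hard labels or per-class fields is genuinely open; fractional one-hot
interpolation is this package's committed choice, with `argmaxVolume`
provided for visualization and NIfTI export.

Slices represent slabs, so the volume extends half a slice thickness
beyond the first and last slice centers by constant extension; without
this the apical and basal slabs would lose half their volume. Gaps
between slabs are spanned linearly with no gap-aware correction. Linear
interpolation of indicators cannot overshoot, so occupancies stay in
[0, 1]; after edge clamping the per-voxel class sums are renormalized to
1 exactly. `structureVolume` is occupancy × voxel volume, in ml.

## Quantification

* LV mass = LV wall volume × 1.05 g/ml, the standard CMR myocardial
  density convention (how mass is derived from a wall segmentation is
  otherwise unspecified in the source cut-offs).
* BSA defaults to Mosteller √(h·w/3600); Du Bois is a config switch.
* Ascending aorta: on each axial plane where the aorta mask (argmax
  rendering) forms ≥ 2 connected components, the most anterior component
  is ascending aorta; its equivalent-circle diameter is 2√(area/π); the
  study value is the maximum over qualifying planes. A single-component
  aorta yields "not measurable" (NA), which is distinct from 0 and maps
  to a FALSE dilatation flag.
* Calibration: ordinary least squares of final on raw, fitted separately
  per scanner manufacturer for the five indexed measures (LVEDVi,
  RVEDVi, LVMi, MVR, indexed aortic diameter). Indexed (not raw) values
  are calibrated — the reported cut-offs are indexed, so that is the
  scale on which the systematic manufacturer bias must be absorbed. The
  mass:volume ratio is calibrated directly by default (it is one of the
  fitted models), with `recomputeMvr = TRUE` available to derive it from
  calibrated components instead. Unknown manufacturers map to an
  "uncalibrated" category whose calibration is the identity.
* Thresholds: LVEDVi > 94 ml/m², RVEDVi > 98 ml/m², LVMi > 83.5 g/m²,
  MVR > 0.84, all strict. The "g/ml" and "ml/cm³" unit strings that
  sometimes accompany these cut-offs in print are treated as typos for
  g/m² and ml/m². No published indexed aortic-diameter or pleural-fluid
  cut-off exists, so `aortaIMax` and `effusionMlMin` are required
  arguments with no defaults; the package's own tests use 17 mm/m² and
  50 ml, which the `dilated_aorta` and `pleural_effusion` presets clear
  by ≥ 15%. For data-driven effusion thresholds, `rocCurve` reports the
  Youden-optimal cut-off over pleural fluid volumes.

## Evaluation statistics

Dice = 2TP/(2TP+FP+FN); two empty masks score 1.0 and are flagged
"vacuous". Cohen's κ = (p₀ − pₑ)/(1 − pₑ) with pₑ from the marginals.
Statistics with empty denominators are absent from results, not NaN.

`reconstructConfusion` inverts printed diagnostic summaries: it
enumerates all integer (TP, FN, FP, TN) with the stated total whose
sensitivity, specificity and accuracy round — half away from zero, at the
precision actually printed (one decimal for "84.3", integer for "80") —
to the stated values. Exact κ values can then be computed from the
solution set; for all five published diagnostic categories the solution
is unique and its κ matches the printed κ at two decimals.

Binomial CIs use the Wilson score interval, chosen because it reproduces
the published detection intervals (9/10 → 59.6–98.2%) where
continuity-corrected and exact intervals do not come close. For 10/10
the Wilson lower bound is 72.247%, sitting at the rounding boundary of
the printed 72.3%.

ROC curves sweep all distinct thresholds with the rule "positive iff
score > t"; AUC is the trapezoidal area, which on the empirical curve
equals Mann–Whitney pairwise concordance (tested exhaustively at small
n). The optimal cut-off maximizes Youden's J, ties resolved to the lower
threshold; accuracy and κ are reported at that cut-off. No binormal
smoothing is applied.

## I/O

The sidecar dialect (a `series.json` manifest plus one 16-bit grayscale
TIFF image and one 8-bit PNG label map per slice) exists so that the full
pipeline round-trips bit-exactly without DICOM fixtures; images are
integer-valued by contract. TIFF rather than PNG carries the 16-bit
image samples because the available PNG writer is 8-bit only; the
manifest, geometry fields and round-trip guarantees are unchanged by
that substitution. A minimal single-frame explicit-VR little-endian
DICOM reader/writer covers the tags the pipeline needs (PixelSpacing,
SliceThickness, ImagePositionPatient, Manufacturer, Rows/Columns,
PixelData); multi-frame, oblique and compressed syntaxes are out of
scope. Reports are versioned JSON with raw + indexed values, one boolean
per flag plus `abnormal_any`, and provenance (thresholds, calibration
id).

## Problem sizes and numerical choices

The test suite builds phantoms on a 180×180×120 mm grid: 1 mm voxels
(≈ 3.9M) where recovery accuracy is asserted, 2 mm voxels elsewhere for
speed. End-to-end recovery is asserted at 2 mm slicing / 2 mm pixels
against a 5% band per structure; an isolated ellipsoid or cylinder
reassembles within 2%. The trainable segmenter is exercised on 200
training / 50 validation / 50 held-out rendered slices at 4 mm thickness,
60 epochs maximum — about a minute of CPU — and is asserted against a
0.80 mean foreground Dice floor (it typically lands near 0.999 under
these conditions, which says more about the phantom's separable
intensities than about clinical imagery). Tie-breaks everywhere resolve
to the lowest class id; volume renormalization tolerance is 1e-6;
calibration requires ≥ 3 points and nonzero raw variance.

## Limitations

Phantom realism is geometric, not radiometric; the trained segmenter's
Dice on phantoms does not transfer to patient scans. The ascending-aorta
rule assumes the ascending and descending segments separate on at least
one axial plane. Calibration absorbs only affine per-manufacturer bias.
Ejection fraction, atrial volumetry and etiologic diagnosis are outside
the package's scope.
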