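---
title: "Relating geometric to dosimetric accuracy of organ-at-risk contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating geometric to dosimetric accuracy of organ-at-risk contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourdose)
```

## The question the package answers

Automatic segmentation of organs at risk (OARs) is normally evaluated with
geometric agreement metrics — volume overlap, surface distances — against a
manually drawn ground truth. But for treatment planning what matters is
whether the *dose* reported to the automatic contour agrees with the dose the
true organ receives. For parallel organs such as the parotid glands and
larynx the clinically relevant quantity is the mean dose, and in modulated
radiotherapy these organs sit in steep, spatially structured dose gradients.
A geometric metric is only useful for quality assurance if it correlates
with the dosimetric error it is meant to guard against.

`contourdose` implements the full analysis chain needed to ask that
question: a voxel-structure data model, the six standard geometric metrics,
STAPLE fusion of multiple observers into a reference standard, mean-dose
extraction with dosimetric-accuracy and interobserver statistics, a pooled
Pearson correlation study, and — because no clinical dataset ships with the
package — a synthetic cohort generator that reproduces the two dose-geometry
regimes in which the question has opposite answers.

## Data model and conventions

Structures are boolean voxel masks on axis-aligned physical grids
(`grid_spec`), with the **voxel-center convention**: voxel `(i, j, k)`
(1-based) is centered at `origin + (c(i, j, k) - 1) * spacing` mm. Every
mm/voxel conversion in the package goes through this one convention, so
metrics and dose sampling cannot drift by half a voxel relative to each
other. Planar polygon contours (the DICOM-RT data shape) are rasterized by
an even-odd rule at voxel centers; a center exactly on a polygon edge counts
as inside (a deterministic tie-break). Structures compared on different
grids are brought together by nearest-neighbor resampling of mask values
onto the reference grid.

A structure's surface is the set of **exposed voxel face centers**
(6-connectivity). This is a deterministic, resolution-controlled surface
model whose positional error is bounded by half a voxel diagonal; the
alternative (marching-cubes meshes) buys smoothness at the price of an
interpolation model that the distance metrics would then inherit. All
surface-distance computations are exact nearest-neighbor queries: each
directed distance equals the all-pairs minimum (the test suite enforces this
against brute-force oracles).

## The six metrics

For an evaluated contour `auto` against a reference `ref`:

* **DSC** `= 2|A∩B| / (|A|+|B|)` from voxel counts — symmetric volume
  overlap.
* **CI** `= V(auto)/V(ref)` — the volume ratio. The orientation is fixed
  (evaluated over reference) so values above 1 always mean oversegmentation.
* **Centroid separation** — Euclidean distance between unweighted centers
  of mass, in mm.
* **meanDTA, maxDTA, 95%-HD** — summaries of the directed
  distance-to-agreement histogram: for every point on the *reference*
  surface, the shortest distance to any point of the evaluated surface. The
  direction follows the definition of DTA from a reference surface; a
  symmetric variant (`dta_histogram_symmetric`) is provided but not used in
  the headline analysis. The 95th percentile uses linear interpolation
  between order statistics (R quantile type 7); the same rule is used for
  interobserver quartiles. The percentile rule is a documented fixed choice —
  nothing in the analysis is sensitive to it, but reproducibility requires
  naming one.

## STAPLE fusion

The reference standard is not a single observer but the STAPLE fusion of
five: an EM algorithm that alternates between estimating the per-voxel
ground-truth probability `W_i` (E-step, from the current rater sensitivities
`p_j` and specificities `q_j` and a scalar foreground prior `g`) and
re-estimating `(p_j, q_j)` from `W_i` (M-step). Numerical choices, all
configurable:

* initialization `p_j = q_j = 0.9999` (conventional high-confidence start);
* prior `g` = mean foreground fraction across raters within the ROI;
* ROI = union of rater masks dilated by 10 mm — an unbounded background
  would inflate specificity toward 1 and stall the EM; the tests verify the
  consensus is insensitive to doubling this margin;
* convergence when the total foreground weight changes by less than
  `1e-5` per ROI voxel, capped at 100 iterations (results are flagged if the
  cap is hit);
* E-step products are computed in log space so five raters cannot
  underflow;
* the binary consensus thresholds the probability map at 0.5, with voxels
  exactly at the threshold included.

On simulated raters drawn from the STAPLE generative model (Bernoulli
sensitivity/specificity channels) the implementation recovers the generating
parameters to within a few hundredths and the consensus Dice exceeds every
individual rater's — both are acceptance-tested.

## Dosimetry

Dose grids are scalar fields in cGy on their own grid. Mean structure dose
is the average of **trilinearly sampled** dose at every foreground voxel
center of the structure — the dose is sampled where the structure lives
rather than resampled onto the structure grid, avoiding double
interpolation. Dosimetric accuracy is the signed percentage difference

> `accuracy = 100 · (meanDose(auto) − meanDose(ref)) / meanDose(ref)`,

negative when the evaluated contour under-reports dose. The per-case
dosimetric interobserver variation (IOV) is the same statistic for each
observer contour against the fused reference; its full min–max range is the
acceptability band, and an auto contour exactly on the boundary counts as
*inside* (the conservative reading of a box-plot whisker; the underlying
per-rater values are retained so any other convention can be applied
downstream).

## The synthetic cohort: what it emulates, and what it does not

Organs are implicit surfaces: a base ellipsoid/superellipsoid radius
function modulated by a seeded low-order spherical-harmonic field
(degrees 1–3, coefficients decaying as `1/l`). For organ *bumps* the field
is normalized to unit peak, so `bumpiness` reads as the largest relative
bump amplitude; for *boundary noise* in the perturbation model the field is
normalized to unit standard deviation, so `boundary_noise_mm` is the sd of
the radial displacement in mm.

Perturbations operate on the structure's signed distance field (exact
separable Euclidean distance transforms with a half-voxel boundary
correction): smooth radial noise shifts the zero level locally, a signed
margin shifts it uniformly (dilation/erosion), and rigid shifts resample the
field trilinearly, so sub-voxel translations behave correctly. The zero
model reproduces the input bit-for-bit.

Dose fields come in the two regimes that make the scientific point:

* **parotid-like** — a single logistic ramp (6500 → 400 cGy, 20 mm
  transition; the logistic scale is `width/4`, so the central 12–88 % of the
  fall-off spans the stated width) whose midpoint sits 8 mm up-gradient of
  the organ center. This places the organ mean dose near 2 200–2 300 cGy,
  the plateau levels and organ mean being guided by typical head-and-neck
  planning constraints (contralateral parotid mean below 2 600 cGy, PTV-like
  high plateau).
* **larynx-like** — two opposing ramps rising away from the organ (3 500 →
  6 500 cGy after rescaling, 15 mm transitions, ramp midpoints 20 mm from
  center) forming a central trough. A rigid shift then trades dose gained on
  one side against dose lost on the other, so position errors barely move
  the mean dose — the mechanism by which centroid separation loses its
  predictive value.

Auto-contour error distributions are regime-specific, and this is the
package's central modelling decision. Parotid-like cohorts use
shift-dominated errors (magnitude uniform on 0–6 mm) whose direction is
biased down-gradient with isotropic jitter, emulating an auto-segmenter that
systematically displaces the gland away from the high-dose region — a
directional bias is required for an unsigned metric (centroid separation)
to correlate with a signed one (accuracy), exactly as a systematic
algorithmic bias underlies the clinical observation. Larynx-like cohorts use
well-localized contours (shifts 0–2 mm, isotropic) with systematic
undersegmentation (uniform margin −3 to −0.5 mm) plus modest boundary noise
(sd 0.5–1 mm): in the opposing-gradient regime the informative error is the
boundary error, which surface metrics see and position metrics do not.
Observers are unbiased: boundary noise of sd 1.5 mm, no shift, no margin,
five per case. Grids are 2 mm isotropic; cohort sizes default to the study
scale (20 parotid-like, 10 larynx-like structures).

What the generator does **not** emulate: CT appearance and observer
window/level behavior, spatially correlated inter-observer style
differences, non-ellipsoidal anatomy topology, deformation over time, and
realistic modulated-fluence dose (fields are smooth analytic ramps). Passing
tests therefore demonstrate that the *analysis chain* is correct and that
the geometric–dosimetric dissociation follows from gradient geometry; they
do not certify any clinical auto-segmenter.

## The study pipeline

Per case, the five observers are fused, the six metrics and the dosimetric
statistics are computed, and a failed case is excluded with a logged reason
rather than aborting the run. Pooled per organ group, each metric is
correlated with dosimetric accuracy (Pearson r; two-sided p from the t
distribution on n − 2 degrees of freedom; significance at p < 0.05 with no
multiple-testing correction — one conventional test per metric, per group).
Structures are pooled as independent observations within a group. With 20
parotid-like structures the mechanism check asks that centroid separation
correlates more strongly than DSC and is significant; with 10 larynx-like
structures, that centroid separation correlates more weakly than meanDTA.
The test suite verifies both over three fixed seeds; at these group sizes a
correlation of ±0.44 (n = 20) or ±0.63 (n = 10) is the significance
boundary, which is why the generator's error distributions must put the
signal where the regime says it belongs rather than relying on sampling
luck.

## Degenerate inputs and tie rules, collected

* Two empty structures: DSC undefined (error); empty evaluated structure:
  CI 0; empty reference: error.
* Empty mask has no surface and no centroid (errors); volume 0.
* DTA needs non-empty clouds on both sides.
* STAPLE rejects empty raters and raters degenerate within the ROI;
  non-convergence is flagged, not hidden.
* Dose sampling outside the grid's voxel-center bounding box is an error
  naming the point; structures poking out of the dose grid error with their
  offending extent.
* Voxel centers on polygon edges are inside; probability exactly at the
  consensus threshold is foreground; accuracy exactly on an IOV whisker is
  inside.

## Problem sizes and determinism

The shipped analysis uses 20 + 10 cases on 2 mm grids (roughly 80 000
voxels per volume), five observers per case; the full pipeline runs in
about two minutes on one core, and every number is a pure function of the
seeds: regenerating a cohort with the same seed reproduces manifests, case
records and correlation tables byte-for-byte. Sub-voxel geometry
(perturbation, dose interpolation) is accurate to roughly half a voxel;
analytic checks in the tests bound the error (centroid of a 3 mm shift
within 0.2 mm, meanDTA of a 2 mm dilation within 0.5 mm).

## Known limitations

* Only axis-aligned grids; oblique acquisitions must be resampled upstream.
* The face-center surface model quantizes distances at fine scales; metrics
  scale linearly with spacing (tested), so finer grids converge, but
  sub-voxel surface detail is not represented.
* Serial-organ (maximum-dose) accuracy is out of scope; the dosimetric
  statistic is the mean dose of parallel organs.
* The signed-distance half-voxel correction assumes near-isotropic spacing;
  strongly anisotropic grids will bias dilation radii toward the mean
  spacing.
* STAPLE is binary, with a scalar prior; no multi-label fusion, spatial
  priors or MRF regularization.
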