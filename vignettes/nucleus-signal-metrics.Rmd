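---
title: "Quantifying signal-intensity distribution in the nucleus pulposus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying signal-intensity distribution in the nucleus pulposus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discmetrics)
```

## The measurement problem

On a T2-weighted sagittal MR slice, a healthy nucleus pulposus appears as a
bright ("high-intensity") zone inside the darker annulus fibrosus. Disc
degeneration dehydrates the nucleus: its signal drops, its shape consolidates,
and the *distribution* of signal within the zone changes before gross
morphology does. `discmetrics` measures that distribution with four scalar
descriptors of the segmented nucleus zone, all defined on the longitudinal
(anterior–posterior) axis of the disc:

* **DX (mm)** — distance along the longitudinal axis between the
  intensity-weighted centre of the zone, $X = \sum_i X_i S_i / \sum_i S_i$
  (with $X_i$ the pixel-centre coordinate and $S_i$ its intensity), and the
  unweighted geometric centre (the same formula with $S_i \equiv 1$).
* **H (mm)** — the nucleus height: the mask's extent perpendicular to the
  longitudinal axis.
* **SM** (arbitrary intensity units) — the maximum, over longitudinal
  positions, of the sum of masked intensities along the perpendicular
  direction.
* **PSM (mm)** — the longitudinal position at which SM occurs.

SM is reported in the scanner's arbitrary units and is not comparable across
scanners or protocols; the mm-valued descriptors are grounded in the pixel
spacing of the acquisition.

## Pipeline

`analyze_disc()` chains four stages.

**Segmentation** (`segment_nucleus`). The zone is detected semi-automatically:
the user supplies one seed pixel inside the nucleus; the region grows over
8-connected pixels whose intensity is at least `threshold_fraction` (default
0.5) of a reference intensity, followed by a 1-pixel morphological closing,
hole filling, and reduction to the seed's component. The reference is the
median of the seed's 3×3 neighbourhood, which makes the reference robust to
single-pixel noise; because the threshold is *relative*, the mask is invariant
to rescaling the image, though not to adding a constant. Raising the fraction
can only shrink the mask. A region that reaches the image border triggers a
`border_leak` warning — containment failed and the caller must decide. A
manual polygon outline (`polygon_mask`, pixel-centre rasterisation) is
accepted as a drop-in replacement for observers who prefer to contour.

**Disc frame** (`estimate_disc_frame`). Only the nucleus is segmented, so the
longitudinal axis is estimated from the nucleus itself: it is the major
principal axis of the mask's second central moments in mm coordinates. The
axis is oriented so its image-x component is positive (anterior ≈ +x in
standard sagittal display; ties toward +y), with the angle reported in
(−90°, 90°]. When the moment eigenvalues are within 5% of each other the
direction is meaningless; the frame falls back to the image x-axis with an
`ambiguous_axis` warning. For wedged discs the axis can instead be supplied as
two points on an endplate line (`axis_points`), and a fully explicit
`disc_frame()` can be passed to `analyze_disc()`.

The frame origin is the posterior-most masked projection onto the axis, so
longitudinal positions (and hence PSM) run from 0 at the posterior end of the
*nucleus* to the nucleus length. This makes the measurement self-contained in
the segmented object and reproducible, at the cost that PSM is invariant to a
pure translation of the nucleus within the disc. Studies of nucleus
*migration* should therefore measure PSM in a common, disc-anchored frame
(e.g. `disc_frame()` at the posterior disc pole) passed explicitly to
`analyze_disc()`; the phantom ground truth records both variants
(`true_PSM_mm`, `true_PSM_disc_mm`).

**Resampling** (`to_disc_frame`). The slice and mask are resampled onto an
isotropic grid (spacing = the smaller input spacing) whose columns index the
longitudinal direction. Intensity uses bilinear interpolation with the
weights restricted to masked source pixels and renormalised — the descriptors
are defined *within* the zone, and unrestricted interpolation would dilute
boundary values with darker annulus signal. The mask is resampled by majority
coverage (interpolated indicator ≥ ½), which preserves binarity and, unlike a
nearest-neighbour lookup, keeps the masked area unbiased under rotation. The
output grid is anchored on the masked projections, so an angle-0 frame
reproduces the input pixels exactly.

Resampling is flux-conserving: a binary mask quantises area, which at oblique
angles drifts the masked total by a few percent in either direction, so the
interpolated intensities are rescaled by the single global factor that makes
the masked total equal its pre-resampling value. The factor is identically 1
at angle 0, leaves DX, H and PSM untouched (they are intensity-scale
invariant), and its raw value is kept in `resample_bias`; a drift beyond 5%
raises a warning as a sign of gross failure (e.g. a degenerate sliver mask).

**Descriptors** (`compute_DX`, `compute_profile`, `compute_SM_PSM`,
`compute_H`). The profile sums masked intensities down each aligned column;
its total equals the masked total exactly. SM ties are broken to the smallest
(posterior-most) position and flagged — ties have probability zero on noisy
data but are certain on synthetic uniform plateaus, where a rasterized
ellipse yields several exactly equal central columns; on such inputs PSM sits
at the posterior edge of the flat top, not at the centre. H defaults to the
maximum column-wise extent; `h_mode = "center"` measures at the column
nearest the geometric centre instead, since the clinical definition of
"height" admits both readings. Pixel centres are the coordinate convention
throughout: pixel (r, c), 1-based, sits at ((c−½)·spacing, (r−½)·spacing) mm.

## The phantom generator and its ground truth

`phantom_spec()` describes a synthetic sagittal disc: an elliptical annulus
plateau on a dark background containing a brighter nucleus ellipse, rasterized
by pixel-centre inclusion at 512×512 over a 320 mm field of view
(0.625 mm/px) by default, with disc semi-axes 20×5 mm and nucleus semi-axes
10×3.5 mm so the height lands in the clinically typical 7–9 mm band. The
default nucleus plateau of 100 puts SM near 1100, the order of magnitude of
real T2 sums with this technique; the scale is otherwise arbitrary. Intensity
inside the nucleus can carry a signed longitudinal gradient (anchored at the
nucleus centre) and a relative centre-bright dome (`intensity_curvature`),
emulating the hydrated nucleus's appearance; noise is additive Gaussian
clipped at zero, which approximates T2 magnitude noise at high SNR. Validation
rejects any spec whose nucleus is not strictly the high-intensity zone or not
contained in the disc.

Ground truth (`phantom_truth`) is computed on the rasterized *noiseless*
image — never from the continuous geometry, because rasterization shifts
centres and extents — by a brute-force oracle that shares no code with the
pipeline: explicit accumulation loops over masked pixel centres for the
centres and DX, and a 4×4-subpixel projection binning for the profile, SM and
PSM. At angle 0 the oracle and the pipeline compute the same discrete
quantity and agree to floating-point precision; this is the package's primary
validation surface (50 random phantoms varying spacing, geometry, offsets,
gradients, dome and plateaus). Rotation behaviour is validated separately:
frame-angle equivariance within 1° across ±60°, exact quarter-turn raster
rotations (metrics within 1 pixel / 1% SM), and segmentation Dice ≥ 0.95
across 0–60° orientations. At general oblique angles both the pipeline's
interpolation and any binning oracle approximate a continuous integral with
discretisation error of a few percent of SM, so oracle agreement is asserted
where the two routes are exactly comparable.

**What the phantom does not emulate**: vertebrae, endplates and surrounding
tissue (the background is flat); partial-volume and bias fields; structured
(non-Gaussian, spatially correlated) MR noise; non-elliptical nucleus shapes
such as the cleaved or collapsed zones of late degeneration. Passing phantom
tests therefore demonstrates the correctness of the measurement chain, not
segmentation robustness on pathological anatomy — on real slices the seed
choice and threshold remain the operator's responsibility, which is why both
are logged in the provenance of every result.

## The cohort effect model

`effect_model()` + `generate_cohort()` simulate a pathology × severity cohort
(spondylolisthesis vs idiopathic scoliosis, severity 1–3, `n_per_cell`
subjects). Per-cell means encode the clinically reported directions:

* nucleus plateau intensity higher for scoliosis (56 vs 97 units), with no
  severity trend — SM separates the pathologies only;
* nucleus half-length larger for scoliosis and decreasing with severity
  (10.2/9.4/6.4 mm vs 15.1/14.0/12.3 mm) — PSM separates both factors;
* nucleus half-height decreasing with spondylolisthesis severity
  (4.46/4.05/3.44 mm vs 3.93/3.81/3.73 mm) — H tracks severity.

Each subject also draws a small intensity gradient (SD 0.5 units/mm) and a
dome strength (N(0.35, 0.08), clipped to [0, 0.6]): real nuclei are not flat
plateaus, and a perfectly flat profile would make the position of the maximum
degenerate. Between-subject SDs (1.5 mm half-length, 0.5 mm half-height, 15
intensity units, 0.5 mm offset) are sized so that a 10-per-cell cohort
detects the encoded effects decisively while cell means stay in the
clinically observed ranges (PSM ≈ 6–15 mm, H ≈ 7–9 mm, SM ≈ 500–1250). Draws
are clipped into the phantom's validity region (containment, zone brighter
than annulus), which slightly truncates the tails.

`generate_cohort(..., slices = FALSE)` skips assembling the full 512×512
rasters and returns ground truths only (computed on the disc's bounding
window, which is identical because the raster is background outside the
disc); simulation studies use this fast path.

## Statistics

`reproducibility_sd()` summarises repeated measurements of one disc with the
sample SD (n−1), pooled and per observer; SM is reported as percent of its
mean so the statement is scale-free. `two_way_anova()` fits the fixed-effects
pathology × severity model with interaction using sum-to-zero contrasts and
Type III sums of squares — the appropriate choice for the unbalanced designs
of retrospective cohorts, and stated explicitly because the SS type changes
p-values when cells are unequal. Severity is treated as categorical, matching
its definition as discretised clinical grades rather than a dose. The
interaction is estimated but reported as supplementary; empty cells drop it
with a warning, a single-level factor is a rank-deficiency error, and a
zero-variance response is flagged degenerate rather than returning misleading
F values. `cohort_report()` lays the cohort out as mean ± SE per cell
(spondylolisthesis 1–3, then scoliosis 1–3); its means equal the ANOVA cell
means exactly.

Two simulation checks calibrate the module, at sizes chosen to run on one
CPU in a few minutes: type-I error of both factors over 1000 balanced null
cohorts (10/cell) must lie in 0.05 ± 0.02, and over 200 default-model
cohorts the pathology effect on SM and both effects on PSM must each be
detected at α = 0.05 in at least 95% of replications. The detection check
runs on cohort ground truths: the oracle-equivalence and reproducibility
results bound the measurement error far below the between-subject SDs, so
pipeline-level power is the same.

## Known limitations

* Discs from the same patient are treated as independent records; no mixed
  model for within-patient correlation is provided.
* No correction for out-of-plane obliquity: a single sagittal slice is not
  the maximum-deformation plane in scoliosis.
* SM is scanner-relative; only within-protocol comparisons are meaningful.
* The nucleus-anchored PSM origin is blind to pure nucleus translation (use
  a disc-anchored frame for migration questions, as above).
* DICOM input is not supported; use NIfTI, PNG + JSON sidecar, or TSV + JSON
  sidecar.
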