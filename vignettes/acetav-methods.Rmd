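---
title: "Measuring true acetabular anteversion on 3D surface models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring true acetabular anteversion on 3D surface models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetav)
```

## The problem

The anteversion (AV) of the acetabulum — the forward opening of the hip
socket — is routinely measured on a single axial CT cut: an angle between
the line across the bony acetabular margins and a perpendicular to a
posterior reference line. That reading is not intrinsic to the bone. It
changes with anterior–posterior pelvic tilt and with lateral rotation of
the pelvis on the scanner table, so the same hip can read several degrees
differently depending on how the patient happened to lie. Retroverted or
borderline sockets can be misclassified, which matters for osteotomy
planning and arthroplasty.

`acetav` measures AV on the 3D surface model instead. Both defining planes
move rigidly with the bone, so the measurement cannot be biased by
positioning.

## The model

**Acetabular plane.** The bony rim of the socket is a sharp, nearly
circular crest. On a triangle mesh it is delineated as the band of highest
surface curvature, and a circle is fitted to that band in 3D. The plane of
the fitted circle, normal oriented out of the cup, is the acetabular plane.

**Anterior pelvic plane (APP).** The plane through the left and right
anterior superior iliac spines and the most forward point of the pubic
tubercles, normal oriented anteriorly. This is the standard coronal
anatomical reference of the pelvis.

**Angle.** With $\alpha$ the angle between the two unit normals,
$\mathrm{AV} = 90^\circ - \alpha$. The sign follows from the oriented
normals: positive when the cup opening tips anteriorly (anteversion),
negative for retroversion. No projection into a transverse plane is
involved; this is the direct angle between planes, which is what makes it
pose-invariant. It therefore differs by construction from projected 2D
quantities such as the classical "anatomical anteversion".

## Pipeline stages and their numerical choices

### Curvature and rim delineation

Per-vertex mean-curvature magnitude is computed with the cotangent
Laplacian and mixed Voronoi vertex areas (Voronoi area in non-obtuse
triangles; $T/2$ at the obtuse corner, $T/4$ elsewhere, otherwise).
Boundary vertices get curvature 0; zero-area triangles are skipped with a
warning. The estimator reproduces $1/r$ on a sphere and $1/2r$ on a
cylinder to within a few percent at the tessellations used in the tests.

`select_rim()` thresholds the field at a percentile (default 90), forms
connected components on the mesh graph and keeps the component nearest a
seed point (the largest one without a seed). Two details matter in
practice:

* **Field smoothing** (default 2 one-ring averaging rounds) before
  thresholding. Measured curvature on noisy surfaces is speckled; the crest
  is a spatially coherent ridge, so averaging raises its contrast against
  speckle. This is a detection device only — the fit uses the original
  vertex positions.
* **Encirclement check**: the angular span of the selected vertices around
  the preliminary circle axis must exceed 300°, otherwise the selection is
  rejected (a rim fit from a short arc would be ill-conditioned, and the
  method is defined on a full ridge circle). Manually delineated rims are
  accepted via `manual_rim()`, mirroring expert-reviewed labelling.

### Robust circle fit

`fit_circle3d()` fits a total-least-squares plane (SVD), projects, runs the
algebraic Kåsa fit as initialisation and then minimises the sum of squared
*true 3D* point-to-circle distances
$d_i^2 = (\rho_i - r)^2 + h_i^2$ (in-plane radial and axial components).
Radius and axial centre offset are profiled out in closed form; BFGS
optimises the axis direction and in-plane centre. The refinement runs in a
canonical frame derived from the data (SVD axes with skewness-fixed signs),
which makes the fit exactly equivariant under rigid motions rather than
equivariant only to optimiser tolerance.

Outliers — osteophyte-like vertices — are removed iteratively: residuals
beyond 3.5 scaled median absolute deviations are dropped and the fit
repeated (at most 5 rounds, both parameters configurable). MAD is used
because gross rim pathology produces exactly the long-tailed residuals that
defeat an RMS criterion. There is no random initialisation anywhere; the
whole chain is deterministic.

Degenerate inputs (fewer than 6 points, collinear points, all points
flagged) raise errors rather than returning garbage.

### The 2D comparator

`compute_av2d()` re-creates the axial reading on the mesh: the cut is the
axial plane at the mean femoral-head-centre height; the mesh–plane
intersection is chained into contour polylines; the acetabular margin
points and (for the posterior-margin variant) the posterior reference
points are obtained by snapping labelled 3D seeds to the nearest contour
point within 10 mm — the deterministic analogue of a radiologist reading
the cut. The angle is measured from the perpendicular of the reference line
to the acetabular-margin line, positive when walking from the posterior to
the anterior rim point moves medially (anteversion).

Two reference variants exist because the clinical literature uses both: the
posterior pelvic margin line (ischial tuberosities or sciatic-notch
margins; the caller supplies either pair, sciatic-notch preferred when both
are present) and the femoral-head-centre line. On a symmetric phantom in
neutral pose the two coincide.

### Pose angles and the tilt experiment

The pelvis pose relative to the scanner is summarised by two angles.
λ (anterior–posterior tilt) is the signed angle, in the sagittal plane,
between the anterior direction and the APP normal; ρ (lateral tilt) is the
signed angle, in the coronal plane, between the inter-ASIS line and the
transverse axis. Both are defined *constructively*: applying a rotation of
+θ about the transverse axis to a neutral pelvis gives λ = +θ exactly, and
a rotation of +θ about the (downward) vertical axis gives ρ = +θ, positive
when the left ASIS moves cranially. We fix the conventions this way because
published regression intercepts for these angles are not mutually
consistent enough to reconstruct a unique parameterisation; with a
constructive definition every sign in this package is testable.

`tilt_sweep()` rotates mesh and landmarks about the midpoint of the femoral
head centres (the natural pivot: both head centres keep their height under
AP tilt, so the cut level is stable), re-selects the cut, re-snaps the 2D
landmarks per pose — re-using the old 2D points would wrongly make the 2D
method look invariant — and recomputes both measurements. With a fixed rim
selection the 3D column is constant to numerical precision; with full
re-detection it varies by well under a degree. The 2D column drifts
monotonically with AP tilt and is also perturbed by lateral tilt. At
extreme lateral tilt the cut can miss the rim seeds; such rows are flagged
`ok = FALSE` rather than aborting the sweep.

## The phantom: exact ground truth by construction

Testing a measurement chain requires geometry whose true answer is known
exactly, so the generator is deliberately *non-anatomical*: a smooth body
ellipsoid (the pelvis bulk, semi-axes 110 × 45 × 70 mm) plus a cup assembly
— a spherical bowl (radius 25 mm, 85% of a hemisphere; the bony socket is
shy of a full hemisphere) meeting a flat annular flange at a perfectly
sharp crest. The crest ring *is* the ground-truth rim circle. The cup axis
is set from the requested anteversion AV and inclination I as
$n = (\cos AV \cos I,\; -\sin AV,\; -\cos AV \sin I)$ (left side, LPS
frame), so the anteversion recomputed from the true planes equals the
requested value to machine precision, for any specification.

Choices worth recording:

* **Inclination default 45°** — a typical acetabular inclination. It also
  produces the 2D overestimation analytically: the axial chord of the rim
  circle satisfies $\tan AV_{2D} = \tan AV / \cos I$, so a socket built
  with AV = 16.1° reads ≈ 22.2° on the slice — the same ≈ 6° gap reported
  between 3D and 2D methods clinically.
* **Graded tessellation.** Ring spacing is finest (0.72 mm) at the crest
  and grows geometrically away from it, which mirrors how curvature-adaptive
  remeshing treats a ridge and keeps the crest band in the top decile of
  the curvature distribution, where the default detection threshold
  operates. The default mesh has ≈ 4 400 vertices.
* **Correlated vertex noise.** Segmentation error on CT surfaces is
  spatially correlated at the voxel scale; white per-vertex noise of the
  same amplitude would produce a surface roughness no segmented bone shows
  and is a pathological input for any curvature estimator. The generator
  therefore smooths white Gaussian displacement over the mesh graph and
  rescales it to the requested SD (default 0 mm; 0.3 mm in the noisy
  tests). All noise flows from a single seed; generation is deterministic.
* **Rim fillet.** `rim_fillet_mm` blunts the crest with chamfer rings, the
  difficulty knob for detection; the default is a sharp crest.
* **Landmarks are exact** (expert-labelled points, not mesh vertices),
  including the analytic rim–slice crossing points used as 2D seeds and as
  the oracle for the snapping test.

What the phantom does *not* emulate: real pelvic shape variation,
incomplete or elliptic rims, osteophytes and pincer deformity, bilateral
asymmetry, CT partial-volume effects. Passing the phantom suite shows the
measurement chain is correct and pose-invariant on well-defined geometry;
it does not certify accuracy on pathological anatomy, where the clinical
workflow falls back to manually reviewed rim delineation (`manual_rim()`).

## The cohort simulator and statistics layer

`make_cohort()` draws a two-sided cohort with the statistical structure of
a hip study population: subject sex (female probability 61/129), per-sex 3D
anteversion (male 14.0 SD 5.4°, female 18.4 SD 5.6°), per-subject pose
angles, and a 2D reading offset by a linear pose bias
$av2d = av3d - (b_0 + b_\lambda \lambda + b_\rho \rho + b_{int}\lambda\rho
+ \varepsilon)$, defaults $b_0 = -36.643$, $b_\lambda = 0.474$,
$b_\rho = -0.318$, $b_{int} = 0$. The pose model
(λ ~ N(65, 7.3)°, ρ ~ N(0, 2)°, ε SD 3.5°) is derived once from those
coefficients together with the target discrepancy moments
(Δ mean ≈ −5.8°, SD ≈ 4.9°) and an explained-variance fraction of
R² ≈ 0.5: the λ mean makes the intercept consistent with the mean bias, the
λ SD supplies the explained variance, and the residual SD supplies the
rest. With these defaults the simulated cohort reproduces the printed
moments of the motivating clinical population without any fitting.

`run_bias_analysis()` runs, per side, the single regressions of
Δ = av3d − av2d on λ and on ρ, the multiple main-effects model, the
interaction model, and the paired 3D-vs-2D comparison. Fits use ordinary
least squares behind a validated wrapper that checks the design rank and
names collinear columns; t-tests are Welch by default (the pooled-variance
variant is available for fidelity checks). Hemipelvises are analysed per
side with no mixed-model correction for the two sides per subject — a
deliberate fidelity caveat, as the motivating analysis used none; the
standard errors for pooled two-side analyses are accordingly slightly
optimistic.

p-values are kept at machine precision in all returned tibbles;
"< 0.0001"-style formatting is a rendering concern.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on generated
geometry: phantoms of ≈ 4 400 vertices, 100 random rigid poses for the
invariance property (25 in the quick acceptance script), 21-step tilt
sweeps, circle fits with 2 500 rim points over 50 seeds, recovery sweeps
over AV ∈ {5, …, 30}° with 50 noisy replicates, and 100-replicate cohort
simulations at n = 129 subjects. These sizes give stable statistics while
keeping a full run in the low minutes on a single core.

## Known limitations

* The rim detector assumes one dominant high-curvature loop around the
  socket; severely degenerate or osteophytic rims need the manual override.
* The 2D seed-snapping emulates, but cannot fully reproduce, a human
  reading of low-contrast cuts.
* The signed-AV convention for retroverted sockets is this package's
  extension; published magnitudes for healthy hips are unsigned.
* The phantom's analytic convenience (symmetric, circular rim) means
  residual-based quality metrics (`fit_rms`) will read optimistically
  compared with clinical meshes.
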