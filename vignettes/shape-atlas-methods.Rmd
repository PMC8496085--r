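---
title: "Methods: biventricular shape atlases, covariate regression and geometric strain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biventricular shape atlases, covariate regression and geometric strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioshape)
```

## Scope and assumptions

cardioshape analyses cohorts of *corresponded* biventricular surface
meshes: every case has the same vertex count and connectivity, per-vertex
anatomical labels, and ED/ES phase pairs. Correspondence is assumed to
come from upstream model fitting (template customization to images);
nothing in this package establishes it, and all statistics are only as
good as that correspondence. The statistical model is linear throughout: a
multivariate Gaussian shape distribution summarised by PCA, and linear
regressions of scores on covariates. Nonlinear shape manifolds, temporal
dynamics beyond the ED/ES pair, and outcome prediction are out of scope.

Units are millimetres, millilitres and grams in a right-handed patient
frame; no axis flipping is applied on I/O.

## Alignment and the atlas

Generalized Procrustes alignment iterates (a) closed-form least-squares
rigid registration of each case's ED points to the current mean and
(b) mean update, until the RMS mean change falls below `tol` (default
1e-6 mm, `max_iter` 100). Only rotation and translation are removed —
no scaling — so overall heart size remains in the shape space and
surfaces as the leading mode. Reflections are projected back to proper
rotations (determinant +1) with a warning; anatomical mirror images are
never legitimate fits. The mean is initialized from the first case in
sorted case-id order; the procedure is insensitive to this choice up to a
global rigid frame, which is also why mode loadings are only defined up
to that frame. The ED transform is applied unchanged to the ES mesh, so
ED→ES motion is expressed in the aligned frame.

PCA uses the economy SVD of the mean-centred `n × 6N` matrix of combined
ED+ES shape vectors; `λ_k = s_k²/(n−1)` and modes are limited to the data
rank. Because PCA signs are arbitrary, each mode is oriented so its
largest-magnitude loading is positive — reproducibility, not anatomy,
dictates this convention. The retained count K is the smallest number of
leading modes reaching the `var_threshold` (default 0.90) cumulative
variance fraction; an explicit `n_modes` overrides it.

Morphometric scores are standardized projections
`z_k = (x − μ)·φ_k/√λ_k`. The standardization is a deliberate design
choice: downstream regressions report standardized parameter estimates,
and unit-variance scores make "PE = score SDs per predictor SD" exact.
Raw-millimetre projections are available (`standardize = FALSE`). ED and
ES blocks are weighted equally in the PCA; no phase is privileged.

## Covariate regression

The design standardizes PRVI, height, weight and age to mean 0/SD 1 and
codes sex and tricuspid-regurgitation grade by treatment contrasts whose
references (female, none-trace) are the most frequent categories in the
emulated cohort. Each mode's score is fitted by OLS separately;
mode-by-mode fitting gives coefficients identical to a joint multivariate
fit because the design is shared. Overall predictor effects use the
partial F-test of the predictor's column block (α = 0.05); for
single-column predictors this is the usual two-sided t-test. No
multiple-testing correction is applied across modes by default — per-mode
raw p-values are the reporting convention here — but a
Benjamini–Hochberg option exists (`p_adjust = "BH"`).

The variance a predictor "accounts for" has no single canonical
definition when combined across modes, so the combination rule is
explicit and configurable: the default `sr2` rule sums, over the
predictor's significant modes, the mode's variance fraction times the
predictor's semi-partial R² (drop-one R² difference) in that mode;
`pe2` substitutes the squared standardized coefficient, and `fsum` counts
the full mode fractions. In the orthogonal single-predictor limit all
agree with `f₁·PE²`.

`shape_at_covariates()` evaluates every mode's fitted regression at the
requested covariate values, with unspecified covariates held at training
means (categorical ones at training frequencies), and reconstructs the
expected shape; at the all-means point this returns `μ` exactly. All
modes' coefficients are used by default — the regression surface — with a
significant-modes-only variant as a flag. Covariates beyond ±4 SD of the
training range trigger an extrapolation warning. Displacement maps sign
the per-vertex Euclidean displacement by the outward normal of the
reference mesh, outward meaning away from the LV cavity; each anatomical
surface resolves its orientation separately since they are disjoint
components.

## Remodeling features

All features derive from the mesh's own reference frame — LV long axis
from the apex landmark to the mitral-ring centroid, base plane through
that centroid — and are therefore exactly rigid-invariant.

* **Basal bulge**: maximal height of RV free-wall vertices above the base
  plane, clamped at 0 (a signed variant exists).
* **Tricuspid tilt**: acute angle between the base plane and the
  total-least-squares plane of the tricuspid-ring vertices.
* **Apical angle**: the four-chamber plane is spanned by the LV apex and
  the mitral and tricuspid centroids — the imaging view is not available
  at mesh level, so the model landmarks define its surrogate. The septal
  line is a TLS fit to the apical third of the septal section curve; the
  free-wall line is the minimal-residual sliding window (default 30% of
  curve length) — an operationalization of "most linear portion", for
  which no published algorithm exists. Both lines are oriented base-ward
  and the angle reported in (0, 180).
* **Dimensions D1–D4**: at `level(0.5)` of the apex-base axis, the septal
  direction is the principal direction of the septal contour segment;
  D1/D3 are LV/RV contour extents perpendicular to it, D2/D4 parallel.

## Geometric strain

Circumferential and longitudinal strains are engineering strains of
section arc lengths; radial strain is the engineering strain of
centerline wall thickness (thickening positive). Base/mid/apex sit at
fractions 0.75/0.50/0.25 of the apex-base axis — named levels only, so
the fractions are configurable — and are recomputed from each phase's own
frame by default (`frame_phase = "ed"` reuses ED planes). The LV
circumferential contour includes the septum; the RV uses the free wall
only. Longitudinal arcs are the longest open endocardial section
polylines (valve-ring boundary to valve-ring boundary through the apex)
in the four-chamber plane and an RVOT plane through the pulmonary and
tricuspid centroids and the RV apex — again a model-space surrogate for
the imaging view. A view that misses a chamber is excluded with a
warning; on the bundled synthetic template the RVOT plane misses the LV,
so LV longitudinal strain comes from the four-chamber view alone.

The wall-thickness variant of the centerline method: endocardial and
outer-wall contours are intersected with the level plane; `m = 50`
equally spaced endocardial stations are matched to their nearest
outer-wall points; the midpoints form the centerline; at each station a
chord perpendicular to the local centerline tangent is cast and the
thickness is the distance between its endocardial and outer-wall
crossings, averaged over stations. The LV outer wall is the epicardium
or, where a chord meets it first, the RV septal endocardium — the septum
is LV wall; the RV is measured across the free wall to the epicardium.
Isolated stations whose endocardial point lies outside the outer contour
(noise-level interpenetration) are dropped; more than 10% outside is a
geometry error. Near the base the section may pass through the aortic
orifice and open the LV contour; the longest polyline is then used, which
keeps ED/ES comparisons consistent.

Reported global values follow the convention of the field: CS and LS as
absolute values in cohort tables (systolic shortening is negative), RS
signed.

## Volumes and mass

Cavity volumes cap each valve orifice by a triangle fan to its ring
centroid and integrate the signed-tetrahedron (divergence-theorem) volume
of the watertight result; face windings are made consistent by a
breadth-first orientation pass and the absolute value taken, so input
winding conventions cannot flip signs. Fan capping was chosen because it
is deterministic, watertight and refinement-independent. Closed-form
checks (spheres, ellipsoids) agree within 0.5% at icosphere subdivision
4. Myocardial mass multiplies wall volume by a configurable density of
1.05 g/ml (standard CMR convention). The LV/RV mass partition follows the
label boundary: the RV share is the free-wall shell, integrated as
per-vertex ray-cast thickness to the epicardium times vertex area, and
the remainder — including the septum — is LV mass. This is one of several
defensible partitions; the choice is documented rather than canonical.
Both Mosteller (default) and DuBois BSA formulas are provided for
indexing, since reports rarely state which was used.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the package is validated under: covariates emulate a
repaired-tetralogy cohort — age lognormal with median 16 y and IQR
12–24, height growth-linked to age (median ≈ 160 cm), weight from a
lognormal BMI, 60% male, TR grades at frequencies 0.65/0.20/0.07/0.08,
and PRVI lognormal with median ≈ 24 and IQR ≈ 14–33 ml/m², clamped at
96. The template is an idealized geometry: truncated-ellipsoid LV
(cavity ≈ 122 ml), offset-ellipsoid RV cut by a tricuspid plane tilted
40° (so tilt has an exact ground truth), carved aortic and pulmonary
orifices, and a single enclosing epicardial ellipsoid. ES contracts the
endocardium affinely about the mitral centroid (radial fraction 0.18,
longitudinal 0.14 — circumferential strain is exactly −18% by
construction, EF ≈ 42%), while each epicardial vertex follows its
nearest endocardial point with its wall offset stretched by 1.25,
planting ≈ +25% free-wall radial thickening.

Two planted deformation modes (global size, septal shift) with a 2:1 SD
ratio mirror the dominance of a size mode over the next mode in real
biventricular atlases. Mode fields are orthonormalized *after* projection
onto the orthogonal complement of the rigid-motion manifold (cohort
translations and linearized rotations acting on both phases), so
Procrustes alignment cannot absorb planted variance. `mode_sds` are
expressed as per-coordinate RMS displacement in mm — the coordinate over
the unit-norm 6N field carries the √(6N) factor — because that is the
scale a reader can picture. Covariate effects are given directly in
standardized units (mode SDs per predictor SD) and the residual mode
variation is rescaled so each mode's total SD equals `mode_sds[j]`;
planted effects are then exactly the standardized PEs the regression
should recover. Draws that collapse a cavity below a fifth of the
template volume are re-drawn (residual excursion and vertex noise) with a
warning and the ground truth updated.

What the generator does **not** emulate: the crescent RV wrapping the
septum (the synthetic RV is a separate ellipsoid), trabeculation and
papillary conventions, spatially correlated fitting error (noise is
i.i.d. per coordinate), valve-plane motion patterns, and any nonlinear
shape-covariate relation. Passing tests therefore demonstrate
correctness of the *statistics and geometry operations* under known
truth, not fidelity of any anatomical claim about real cohorts.

## Numerical choices

* Plane-surface intersections nudge exactly-on-plane vertices by 1e-9 of
  the coordinate scale, so every crossing triangle yields exactly one
  segment; segments are chained through shared mesh edges (exact keys, no
  coordinate rounding).
* TLS line/plane fits use the SVD; a collinear tricuspid ring (second
  singular value at rounding level) is a degenerate-fit error.
* GPA's objective (mean squared distance to the mean) is checked
  non-increasing; convergence tolerance 1e-6 mm.
* Zero-variance cohorts yield a K = 0 atlas with a warning; requesting a
  score on a zero-variance mode is an error rather than an Inf.
* The pipeline (`run_pipeline()`) is a pure function of (inputs, config,
  seed); reports are byte-identical across reruns. Per-stage content-hash
  caching was considered and dropped — every stage re-runs in seconds at
  package scale — but output checksums are recorded in the run log.
* Random substreams (covariates, modes, noise, rigid, redraw) derive
  named sub-seeds from the spec seed, so partial regeneration is
  reproducible.

## Problem sizes

The test suite and the acceptance script run the template at 12×24
angular resolution (≈ 1 000 vertices, 6N ≈ 5 800) with cohorts of 16–200
cases, 20-seed regression recovery at n = 300, and a 1 000-replicate null
calibration; these sizes were chosen so the whole validation executes in
a few minutes on one CPU while keeping Monte-Carlo error well inside the
asserted tolerances. All statistical tolerances are 3 standard errors of
the quantity under test; geometric tolerances are stated per feature
(0.2 mm distances, 0.5° angles, 0.5% volumes).

## Known limitations

* Correspondence quality is assumed, not verified; systematic fitting
  bias propagates directly into modes and scores.
* The four-chamber and RVOT planes are landmark-defined surrogates for
  imaging views; absolute feature values can differ from view-based
  measurements even for identical geometry.
* The attribution figure is rule-dependent by construction; compare
  across rules before interpreting a single percentage.
* Mass partition at the septal label boundary assigns the whole septum to
  the LV; RV mass is correspondingly conservative.
* The apical-angle window fraction (0.30) is an interpretation of "most
  linear portion"; sensitivity to it should be checked on real data.
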