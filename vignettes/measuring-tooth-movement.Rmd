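---
title: "Measuring orthodontic tooth movement from serial dental cast scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring orthodontic tooth movement from serial dental cast scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castmove)
```

## The measurement problem

Clear-aligner treatment plans a tooth movement in software; the movement
the patient actually experiences is smaller. Quantifying that gap requires
comparing three 3-D models per patient: the pre-treatment cast (T1), the
cast taken after the analyzed treatment phase (T2), and the virtual
planned outcome (ClinT2). castmove implements the measurement chain that
turns these three labelled point clouds into clinical movement components
and a treatment efficacy:

1. **Reference-teeth superimposition.** T2 and ClinT2 are each mapped
   into T1's coordinate system by trimmed iterative-closest-point (ICP)
   registration restricted to the *untreated* teeth. In a split-mouth
   design only one tooth per hemiarch moves, so the remaining teeth form
   a rigid "corresponding structure" between timepoints.
2. **Per-tooth rigid registration.** The moved tooth's T1 points are
   registered onto its superimposed T2 (or ClinT2) points, yielding one
   rigid transform per tooth and timepoint.
3. **6-DOF decomposition.** Each transform is decomposed, in a
   patient-specific arch frame, into three translations (Tx, Ty, Tz, mm)
   and three rotations (Rx, Ry, Rz, degrees).
4. **Efficacy.** The achieved primary component is divided by the
   predicted one: `efficacy = 100 * achieved / predicted`, signed, so a
   wrong-direction movement is negative and overshoot exceeds 100%.

The primary component is fixed by the movement group: molar
**distalization** is a translation along x, incisor **torque** a rotation
about y, premolar **derotation** a rotation about z.

## The arch coordinate frame

For each moved tooth an orthonormal right-handed frame is built from the
reference-tooth centroids:

* **z** is the unit normal of the least-squares plane through the
  reference centroids (the occlusal plane), pointing occlusally.
* **x** is the tangent of a quadratic arch curve fitted through the
  centroids (in the plane's principal-axis coordinates), evaluated at the
  arch position nearest the moved tooth and signed distally — away from
  the fitted parabola's apex, i.e. away from the arch midline.
* **y = z × x** completes the right-handed system.
* The origin is the moved tooth's T1 centroid, which is also the rotation
  centre of the decomposition. The rotation centre matters because the
  translation components of a rotating tooth depend on it; fixing it at
  the T1 crown centroid is a convention, stated here because results are
  not comparable across different centre conventions.

Two sub-choices deserve justification:

**Occlusal sign.** A plane normal has two orientations and the centroids
alone cannot distinguish them. When `build_frame()` is given the cast's
crown points it orients z by a taper statistic: crowns are widest at the
gingival margin and narrow toward the cusps, so the covariance between
height above the centroid plane and in-plane radial spread about the
nearest tooth centroid is negative in the occlusal direction. The rule is
equivariant under rigid motion of the cast — a requirement, since the
whole pipeline must be invariant to how the cast happened to sit in the
scanner. Without crown points a fixed axis convention is used (largest
normal component positive), which is deterministic but *not* equivariant;
the pipeline always passes crown points.

**Euler convention.** Rotations are factored with fixed axes in x → y → z
order (`R = Rz Ry Rx`). The studied movements are dominated by a single
axis, so cross-convention differences are second order, but one
convention must be pinned for reproducibility. Near gimbal lock
(|Ry| = 90°) Rx is set to 0 by convention and the result flagged.

## Registration machinery

`kabsch()` is the closed-form SVD superposition of row-paired point sets,
with the reflection case corrected via the sign of the smallest singular
direction, so the result is always a proper rotation. Collinear or
coincident configurations (cross-covariance rank < 2) are rejected.

`icp()` alternates exact nearest-neighbour correspondence (a k-d tree
with ties broken toward the lowest reference index), rejection of the
`trim_fraction` worst pairs, and a Kabsch fit on the survivors. The
trimmed RMS is non-increasing across iterations; iteration stops when its
relative change falls below `rel_rms_tol` (default 1e-8) or after
`max_iterations` (default 100).

Parameter defaults and why:

* `trim_fraction = 0.1` for cast-to-cast superimposition: casts differ
  slightly outside the teeth (gingival margins, segmentation edges), so
  robust rejection is required.
* `trim_fraction = 0` for per-tooth measurement: both clouds are the same
  segmented tooth at two timepoints, so every point has a true
  counterpart — and trimming actively harms, because the highest-residual
  points under a rotation mismatch are exactly the cusp features that
  drive rotation recovery. This was observed directly: a 20° derotation
  registers to machine precision untrimmed and stalls at ~2.5° with 10%
  trimming.
* Initialization: superimposition starts at centroid alignment (cast
  poses differ little between scans). Per-tooth registration starts
  twice — centroid alignment, and principal-axes alignment with axis
  signs fixed by third central moments — and keeps the fit with lower
  final RMS. Centroid alignment alone is insufficient: planned
  derotations reach 30°, outside its convergence basin for near-round
  premolars. Both starts are deterministic; an exhaustive multi-start
  over SO(3) remains out of scope.

Measuring the *predicted* movement from the ClinT2 scan with the identical
pipeline — rather than trusting the plan numbers in the manifest — lets
any systematic pipeline bias cancel in the efficacy ratio.

## The synthetic cohort generator

No raw per-patient casts are publicly available for the emulated study,
so validation runs on synthetic arches with known ground truth. The
generator places 14 labelled crowns (FDI numbering) on a parabolic arch
curve (width 50 mm, depth 40 mm, crown height 8 mm). Crowns are tapered
superellipsoid shells — faceted cross-sections for incisors, rounded for
premolars, the shape that makes clinical derotation hard — with a smooth
bucco-lingual/mesial asymmetry and a cusp/ridge occlusal relief (paired
cusps for premolars and molars, an incisal edge for incisors, buccal cusp
dominant). The relief is not cosmetic: a crown without occlusal structure
is nearly a surface of revolution and carries no rotational signature for
any registration algorithm, which real crowns do not resemble.

Study conditions emulated, with sources in the published summary tables
(`reference_planning_table()`, `reference_efficacy_table()`):

* **Split-mouth design**: one moved tooth per hemiarch, one subgroup per
  side, all other teeth static; upper jaw only (all three studied
  movements are maxillary).
* **Planned magnitudes** drawn uniformly from intervals matching the
  published mean planned movements: derotation 17.8°/20.1°, torque
  16.1°/15.9°, distalization 2.7/2.6 mm, with subgroup-specific maxima.
* **Staging** fixed per subgroup at the published means, capped at the
  protocol limits (2°/aligner derotation, 1°/aligner torque,
  0.25 mm/aligner distalization).
* **True efficacy** drawn from a normal with the published subgroup
  means/SDs, truncated to [−0.25, 1.25] — the published outcomes range
  from −2.9% to 108.7%, so the generator must admit negative and >100%
  efficacies.
* **Scanner noise**: isotropic Gaussian, σ = 20 µm per coordinate,
  the quoted accuracy of cast laser scanners, added independently to all
  three scans.
* **Compliance** recorded as the prescribed 22 h/day.

Seeds are explicit function arguments everywhere; the generator never
touches global RNG state beyond a save/restore, and identical
configuration plus seed reproduces scans and manifest bit for bit.

What the generator does *not* model — and therefore what passing tests do
not demonstrate about real data: anatomically realistic crown surfaces,
gingiva and palate, segmentation errors at the tooth boundary, relative
drift of the reference teeth under periodontal anchorage (an acknowledged
limitation of the clinical method itself), impression/plaster distortion,
and scanner occlusion artefacts. Tests establish that the measurement
chain is correct for rigid movements under isotropic noise, not that a
real cast pipeline achieves the same error floor.

## Statistics

`summarize_group()` reports n, mean/highest/lowest accuracy in percent,
and the sample standard deviation of the efficacy *ratio* — a
dimensionless fraction, so `sd = 0.2` means 20 percentage points. This
mixed convention mirrors how the clinical tables print "mean accuracy
37.5, SD 0.3" and is stated here because it is easy to misread.

`overall_efficacy()` is the **unweighted** mean of subgroup mean
accuracies. With the published subgroup means it reproduces the quoted
59.3% exactly, whereas a movement-count-weighted mean gives ≈57.5%; the
unweighted convention is therefore implemented and flagged.

The paired t-test compares achieved against predicted movements per
subgroup (two-sided, p ≤ 0.05); its sign convention makes
under-achievement negative. Identical vectors return t = 0, p = 1;
nonzero constant differences are reported as a degenerate test rather
than a number. Normality is checked with Shapiro-Wilk, delegated to the
standard library routine. Derotation records are additionally split at
15° planned amount and 1.5°/aligner staging; values exactly at a
threshold go to the lower bin (the published tables print strict
inequalities with no boundary rule, so one is fixed for determinism).
No multiple-testing correction is applied, matching the emulated
analysis.

## Numerical choices and degenerate inputs

* Rigid transforms are validated at construction: ‖RᵀR − I‖∞ < 1e-9 and
  det(R) = 1 ± 1e-9; serialized transforms are checked on read at 1e-6
  and re-orthonormalized through an SVD before the strict constructor.
* PLY coordinates are written as doubles; float32 cannot hold a 1e-6 mm
  round-trip at 30 mm coordinates.
* Nearest-neighbour ties break toward the lowest reference index; the
  k-d tree visits the far subtree when the splitting-plane distance
  *equals* the current best, so the tie rule survives traversal order.
* Readers reject malformed input (count mismatches, non-finite
  coordinates, non-rigid matrices) rather than repairing it.
* Degenerate geometry raises classed errors: fewer than 3 point pairs or
  rank-deficient cross-covariance (Kabsch), collinear reference centroids
  (frame), fewer than 3 shared reference teeth (superimposition), a moved
  tooth inside the reference set (anchoring).

## Problem sizes

The validation cohort uses 25 patients per movement group — 50
split-mouth movements per group — at 300 surface points per tooth, the
size at which the recovery statistics stabilize: mean absolute error
≈ 0.03° on rotations and ≈ 0.002 mm on translations under 20 µm noise,
group-mean efficacy recovered within < 0.1 percentage points of the drawn
truth. Single-axis noiseless round-trips (apply a movement, re-measure
it) are exact to < 1e-6 in every component.

## Known limitations

* Point-to-point ICP only; point-to-plane and non-rigid registration are
  out of scope, as are scale estimation (casts are metrically true) and
  exhaustive global initialization.
* The efficacy of a movement is scored on its primary component only;
  off-axis side effects (e.g. tipping during distalization) are reported
  in the record's six components but do not enter the efficacy ratio.
* Reference-teeth drift is not modelled or corrected; the superimposition
  inherits this limitation from the clinical method.
* The generator's efficacy distributions are calibrated to published
  group means and SDs only — no per-patient raw values exist to validate
  higher moments.
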