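---
title: "Morphometry of the cardiac conduction system in the thoracic frame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of the cardiac conduction system in the thoracic frame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsmorph)
```

## The problem

The cardiac conduction system (CCS) — the sinus node (SN), the
atrioventricular conduction axis (AVCA: compact AV node, penetrating and
branching bundle of His) and the right and left bundle branches (RBB, LBB) —
is invisible on clinical imaging, yet interventions such as ablation and
device implantation need to know where it runs. Cadaveric morphometry has
shown that the orientation of the CCS components co-varies with the
orientation of the heart itself within the thorax, so the visible cardiac
silhouette can be used to estimate the invisible conduction axes. `ccsmorph`
implements that analysis as a reusable, tested pipeline:

1. a thoracic body-axis frame, rigid rotations about the body axes, and
   signed projection-angle measurement in the three body planes;
2. extraction of anatomical reference axes from named 3D landmarks;
3. the eight bivariate regressions linking cardiac inclination to CCS
   component inclinations, with prediction, refitting and
   parameter-recovery machinery;
4. a stepwise standing-to-lying rotation simulation with per-plane
   classification of concomitant versus counter rotation;
5. a seeded synthetic-cohort generator emulating the 23-heart study data,
   so every stage can be exercised and validated without access to the
   original CT scans (which were never deposited).

## Frame and view conventions

All geometry lives in a right-handed thoracic frame with origin at the
center of the aortic valvar orifice: `+x` toward the subject's left, `+y`
dorsal, `+z` cranial. The three body planes are viewed as a reader of
clinical images would view them — sagittal from the subject's right, frontal
from the front, horizontal from above.

Each view measures a signed angle from a stated reference line, wrapped to
[0°, 360°):

| plane      | in-plane components | reference line                   | positive sense      |
|------------|---------------------|----------------------------------|---------------------|
| sagittal   | (y, z)              | horizontal (dorso-ventral) line, `+y` | toward cranial |
| frontal    | (x, z)              | vertical sagittal line, `+z`     | toward subject's left |
| horizontal | (x, y)              | horizontal line `+x` (cardiac, SN) or sagittal line `+y` (AVCA, RBB, LBB) | `x` toward `y` |

The source morphometry defines its reference lines only verbally, and the
positive rotational senses are only inferable from figure arrows, so the
table above is a package convention, chosen once so that (i) every published
mean angle value is representable and (ii) a positive rotation about each
plane's normal (`rotation_matrix()`, a standard right-handed rotation about
`+x`, `+y`, `+z` respectively) advances every in-plane angle by exactly the
rotation angle. The composed three-axis rotation
(`compose_standing_lying_rotation()`) applies extrinsic rotations about the
fixed thoracic axes in the documented order sagittal → frontal → horizontal;
the order is configurable, and all properties tested here are
order-independent.

Angles are measured on 3D axes first and then projected; the alternative
(measuring on 2D maximum-intensity projections) is indistinguishable for
straight axes, which is all the package measures.

## Reference axes

`extract_reference_axes()` implements the anatomical definitions:

* **cardiac axis** — from the aortic valve center to the left-ventricular
  apex;
* **SN axis** — the line through the SN head center, the top of the terminal
  crest and the aortic valve center, oriented head → valve. Three points
  over-determine a line, so it is fitted by total least squares (first
  principal axis of the centered points), and the RMS orthogonal residual is
  reported;
* **AVCA axis** — from the end of the compact AV node to the branching point
  of the RBB, the straightest part of the conduction axis. The RBB and LBB
  angles (`gamma`, `delta`) are measured in the horizontal plane only,
  because the distal branches curve too much for a 3D axis to be meaningful.

## Over-determined projection angles

A central numerical fact shapes both the generator and the canonical
geometry: **a 3D axis has two rotational degrees of freedom, but three plane
projection angles are reported for it.** One direction's three plane angles
always satisfy a tangent-ratio identity (the product of the three in-plane
component ratios is 1), and the published mean triples do *not* satisfy it —
under any assignment of reference lines and senses, the cardiac mean triple
(99.8°, 46.8°, 61.5°) is not the projection of any single direction. That is
not an error in the data: per-plane cohort means of angles of different
hearts need not be projections of a common mean axis, and each plane's angle
was measured against its own reference convention.

The package therefore treats the per-plane angles as the primary objects and
reconstructs 3D axes by least squares. `ls_direction_from_plane_angles()`
expresses each target angle as the constraint that the axis be orthogonal to
the in-plane vector perpendicular to the target direction, accumulates the
constraint scatter matrix, and takes the smallest-eigenvalue eigenvector —
a weighted circular least-squares fit (each plane's angular residual is
weighted by the axis' projection magnitude in that plane) that is **exact**
for internally consistent angle sets. The sign of the eigenvector is fixed by
requiring the projections to point along, not against, the targets; the
angular RMS residual is always reported. `build_canonical_geometry()` uses
this fit for the cardiac, SN and AVCA axes and records the residuals in the
geometry's provenance: zero (to machine precision) for consistent requests,
a reported diagnostic — never an error — otherwise.

One geometric consequence is worth stating explicitly: no direction can
measure 0° in all three planes at once (it would have to lie along three
reference lines lying in three different planes), so there is no "all-zero
pose". The identity checks in the test suite are therefore per-plane: a
vector along a plane's reference line measures 0° in that plane, and any
internally consistent angle set round-trips through geometry construction
and re-measurement to within 10⁻⁶ degrees.

## The synthetic cohort generator

`sample_cohort()` emulates the published 23-heart morphometry. Its defaults
*are* the study conditions; they are not tuning knobs.

* **Cardiac angles**: independent normals per plane with the published
  marginal means/SDs — sagittal 99.8 ± 12.1°, frontal 46.8 ± 8.1°,
  horizontal 61.5 ± 13.4°. All three are sampled (rather than two sampled
  and the third derived from the reconstructed 3D axis) because, given the
  inconsistency described above, a derived third angle would land tens of
  degrees away from its published marginal mean; sampling per-plane keeps
  every marginal faithful to the study, and the reconstructed axis carries
  the consistency residual in provenance.
* **CCS angles**: per-plane, from the matching regression line anchored at
  the marginal means, `y = mean_y + slope (x − mean_x) + ε`, with
  `ε ~ N(0, σ²)` and σ calibrated by the variance-addition law
  (`calibrate_residual_sd()`: `σ = sqrt(sd_y² − slope² sd_x²)`), so that the
  generated marginal CCS spreads match the published ones. The mean-anchored
  form is used for generation because one printed equation (horizontal SN)
  does not pass through its printed means (0.481·61.5 − 244.2 ≠ 272.4, even
  modulo 360); the printed intercepts remain the defaults for prediction and
  for the through-the-means checks, and the inconsistent pair is flagged
  (`consistent = FALSE`) and excluded from strict consistency assertions.
  Where the running text and the summary table of the source disagree on a
  mean (proximal AVCA sagittal 34.5° vs 31.9°, frontal 147.2° vs 32.9°, LBB
  120.2° vs 117.1°), the text values are the defaults: they satisfy the OLS
  through-the-means identity with the printed equations.
* **Dimensions**: each component dimension (e.g. SN length 33.9 ± 7.8 mm,
  range 20.5–53.5 mm) is drawn from a normal truncated to the printed range
  by rejection sampling. The bundle of His is not sampled separately: it
  spans the compact-node end to the RBB branching point, with length
  PBH + BBH.
* **Angles are generated on the contiguous branch around each mean**
  (e.g. the horizontal SN angle around 272°), raw and unwrapped, so ordinary
  linear regression applies without circular statistics; the cohort spreads
  are far too narrow to cross the wrap point.
* **Seeding**: one master integer seed; independent substreams are derived
  per stage (angles, dimensions, recovery replicates) so adding a stage
  never shifts existing draws. Identical parameters and seed give
  byte-identical outputs.

The fixed scaffold lengths that the study does not print are nominal adult
values, chosen once: cardiac axis 90 mm, SN head 45 mm and terminal-crest
top 25 mm from the valve center along the SN line, compact-node end at
(−5, 5, −5) mm near the aortic root, and 15 mm RBB/LBB measurement segments
with a mild caudal tilt. Projection angles are insensitive to all of them;
displacement magnitudes scale with them.

## Regressions and parameter recovery

`fit_ols()` is ordinary least squares (`stats::lm`), reporting slope,
intercept, residual SD (`sqrt(SSE/(n−2))`), and R²; regression is on raw
degree values, matching the published linear fits. `fit_all_pairs()` applies
the published pairing — each SN/AVCA angle against the cardiac angle of the
same plane, RBB/LBB against the horizontal cardiac angle only.
`regression_through_means()` exercises the through-the-means identity on the
printed equations: six pairs reproduce their printed means to one decimal;
the LBB pair agrees to 0.2° (coefficient rounding); the horizontal SN pair
is flagged as inconsistent as printed. Reported angles are rounded half away
from zero to one decimal, matching the source's presentation.

`recover_parameters()` is the validation harness: it simulates many cohorts,
refits all eight regressions on each, and reports mean estimate, bias, RMSE
and Monte-Carlo standard error per pair. At the study size (n = 23) the
slope estimates are unbiased within Monte-Carlo error, and RMSE shrinks as
cohort size grows — the test suite checks both at 60–1000 replicates, and
`scripts/acceptance.R` reruns the 1000-replicate experiment from scratch.

## The standing-to-lying simulation

`simulation_grid()` defines five poses at k ∈ {−2, −1, 0, +1, +2} times the
per-axis SD (12.1°, 8.1°, 13.4°) away from the mean pose — absolute offsets
from the mean, not cumulative steps. Standing is the k = −1 pose and lying
the k = +1 pose. Two explicit simulation modes resolve an apparent paradox
in the source analysis (a rigidly rotated structure that nevertheless
"counter-rotates" in one 2D projection):

* **rigid** — the whole heart + CCS rotates as one body about a pivot (what
  a DICOM-viewer volume rotation physically does). All inter-landmark
  distances are conserved to 10⁻⁹ relative, and a horizontal-only rotation
  shifts every horizontal-plane angle by exactly the applied increment. When
  all three axes rotate at once, however, each 2D projection is altered by
  all three rotations, so a projected angle can move against its plane's
  nominal rotation — and with the least-squares compromise base direction
  the X-angle sequences are not even guaranteed monotone in k at the grid
  edges.
* **regression** — cardiac angles move plane-by-plane by the grid increments
  and each CCS angle is propagated from the *measured base pose* along its
  fitted slope, `ccs(k) = ccs(0) + slope · (X(k) − X(0))`. Propagating
  offsets (rather than evaluating the raw printed equations) guarantees both
  modes reproduce the base measurement exactly at k = 0, whatever the base
  geometry. In this mode the frontal AVCA trajectory has slope −0.733 and is
  classified **counter**, while all three SN pairs are **concomitant** —
  the published finding.

`classify_rotation_direction()` takes the sign of the least-squares slope of
the (unwrapped) component angle against the (unwrapped) cardiac angle of the
same plane: positive = concomitant, negative = counter, |slope| < 0.01
deg/deg = flat (a numerical guard, not a published value).

`standing_lying_comparison()` pairs the k = ±1 poses and reports, alongside
the angle table and classifications, the displacement of the SN head and of
the AVCA midpoint. The default rigid pivot is the `venous_anchor` landmark,
placed dorso-cranial to the SN head where the pulmonary veins and venae
cavae tether the sinus node (falling back to the aortic valve center if
absent). This choice encodes the anatomy the source describes — the SN held
nearly fixed by its venous attachments while the ventricles containing the
AVCA swing freely — so the AVCA displacement exceeds the SN displacement via
plain lever-arm geometry. With a pivot at the valve center the ordering
would invert, since the SN head sits farther from the aortic valve than the
bundle of His; displacements, unlike angles, depend on the pivot, and the
pivot is configurable.

## Numerical choices

* Exact geometric assertions (rotation rigidity, projection idempotence,
  angle round-trips) at 10⁻⁹; generator round-trips at 10⁻⁶ degrees.
* Degenerate projections (axis within 10⁻⁹ of a plane normal) raise a typed
  error in measurement contexts and are recorded as `NA` with a warning in
  simulation contexts.
* The least-squares axis fit breaks the ±v eigenvector tie by the sign that
  aligns the projections with the targets.
* Truncated-normal rejection sampling is vectorized with a hard iteration
  guard; at the published parameters the acceptance rate per cell is > 85%.
* Problem sizes used by the checks: marginal fidelity at n = 10⁵ (2%
  relative), parameter recovery at 1000 replicates of n = 23, RMSE
  consistency at n = 23 vs 230.

## What the synthetic data does and does not show

The generator reproduces the *statistical* structure of the study — marginal
angle distributions, the regression linkage with calibrated residual noise,
dimension ranges — not the anatomy of any real heart: no atrial or
ventricular wall geometry, no Purkinje network, no valve leaflets, no
age-related degeneration, and no soft-tissue mechanics (the differential SN
vs AVCA mobility is encoded by the pivot choice, not modeled). Passing tests
therefore demonstrate that the measurement, regression and simulation
machinery is correct and internally consistent under the published study
conditions; they cannot certify performance on real CT-derived landmarks,
where landmark identification error, non-rigid deformation and deviations
from normality would add variance the generator does not emulate. The
per-plane regressions themselves are ordinary linear fits, valid on the
contiguous angle branches observed in the study; extrapolating them far
outside the sampled cardiac angle ranges (roughly ±2 SD) has no support.
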