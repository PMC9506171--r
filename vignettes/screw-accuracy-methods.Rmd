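---
title: "Methods: 3D planned-versus-actual accuracy of navigated pedicle screws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D planned-versus-actual accuracy of navigated pedicle screws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navscrew)
```

## The problem

In CT-navigated spinal instrumentation the surgeon plans each pedicle screw
as a virtual trajectory on an intraoperative CT (the *navCT* frame): a head
point at the cortical entry, a tip point in the vertebral body, and the
implant's length and diameter. The implanted screw is later segmented on a
postoperative control CT (the *controlCT* frame). Most of the literature
reports only categorical screw position within the vertebra
(Gertzbein–Robbins grades); the sharper question is how faithfully the
*planned trajectory* was transferred to the patient. Answering it requires
(i) a rigid co-registration of the two CT frames, (ii) per-screw 3D
deviation metrics, (iii) a reading of the categorical grade that can be
computed rather than eyeballed, and (iv) statistics that compare the
observed deviations with the navigation system's own registration error.
`navscrew` implements that chain, plus a synthetic cohort generator so the
whole pipeline can be exercised and validated without patient imaging.

## Deviation metrics

For a paired planned screw $p$ and final screw $f$, expressed in one frame
after co-registration, the package computes

* head and tip point deviations as Euclidean distances (the field calls
  them *minimal absolute distances*, MAD):
  $\mathrm{MAD} = \sqrt{d_x^2 + d_y^2 + d_z^2}$;
* the angular deviation of the screw axes, with the axis defined head→tip
  (the drill path): $\theta = \arccos(\hat u_p \cdot \hat u_f)$, reported
  in $[0^\circ, 180^\circ]$. Values above $90^\circ$ are flagged as
  anomalies but not folded, since planned and final screws are never
  antiparallel in practice. (Published method descriptions sometimes lump
  the angle under the "Euclidean distance" wording; the arccos of the dot
  product is the only well-defined reading and is what we compute.)
* length and diameter differences (final − planned), compared by their
  means across the cohort.

All points, directions and transforms carry an explicit frame tag
(`"navCT"`, `"controlCT"`); any operation mixing frames stops with a frame
error rather than silently producing a number. Coordinates are millimetres
in a right-handed LPS-style patient frame.

## Rigid registration and its error metrics

Both the intraoperative patient registration (point-to-point on at least
three small reference screws placed on the laminae) and the
navCT↔controlCT co-registration are represented as landmark-based
least-squares rigid fits: centroid alignment followed by SVD of the
cross-covariance, with the determinant-sign correction that prevents a
reflection solution under noise. In the clinical workflow the
CT-to-CT alignment is an intensity-based image registration; no image
volumes enter this package, so paired per-vertebra landmarks stand in for
it — the downstream mathematics only needs the rigid transform. The fit
reports

* **FRE** (fiducial registration error): RMS of post-fit residuals at the
  fitted landmarks;
* **TRE** (target registration error): the **mean** (not RMS) Euclidean
  distance at held-out targets, matching how navigation systems report a
  mean registration error.

Co-registration quality is verified per spinal level: the RMS residual of
each level's landmarks is compared with a threshold $\tau$ (default
2.0 mm — a package decision; the clinical verification is visual and
publishes no number). A level strictly above $\tau$ is flagged, and under
the default policy any flagged instrumented level excludes the whole case,
emulating how cases with cranial-segment co-registration failures are
dropped from accuracy analyses. Both $\tau$ and the policy are arguments.

## Geometric Gertzbein–Robbins surrogate

The published grading is a blinded visual consensus of "mm of cortical
breach". The only computable reading is geometric: the pedicle is modelled
as an elliptical cylinder (the safe corridor: axis point + direction,
transverse and sagittal semi-axes, and an axial extent covering the
pedicle segment), the screw as a finite cylinder from head to tip (tip
taper ignored — conservative), and the breach as the maximum signed
distance of the screw surface outside the corridor boundary, evaluated
only within the corridor's axial extent. Negative values are clearance.
Grades follow the breach depth: A $\le 0$ mm, B $(0,2)$, C $[2,4)$,
D $[4,6)$, E $\ge 6$; A and B are clinically acceptable. The boundary
convention (B open at 2, C closed at 2) follows the verbatim grade
definitions.

Numerics: the screw surface is sampled at 100 axial × 36 angular stations
by default; angular phases are staggered across axial stations
(golden-ratio offsets) so the sampled maximum resolves the analytic
parallel-cylinder value to well under 0.01 mm at the default density. The
circle basis at each station is derived from the corridor's own frame
projected perpendicular to the screw axis, which makes the sample point
set — and therefore the breach value — exactly equivariant under a common
rigid transform of screw and corridor. Point-to-ellipse distance is solved
by a vectorized bisection of the standard auxiliary equation (exact closed
form on circular cross-sections). Because the spec of an ellipse by two
semi-axes alone does not orient its cross-section in 3D, corridors carry a
reference direction (`ref_dir`, default cranio-caudal) that fixes the
sagittal axis and transforms with the corridor.

## Statistics

The battery mirrors conventional reporting in this literature: pooled
two-sample $t$ (Welch by flag), one-way ANOVA with Holm–Šidák step-down
post-tests ($\tilde p_{(i)} = 1-(1-p_{(i)})^{m-i+1}$ with a running
maximum), Pearson $\chi^2$ without continuity correction, and
Kruskal–Wallis with mid-rank tie correction. All tests are two-sided at
$\alpha = 0.05$. The implementations are self-contained so the test suite
can verify them against base R (`t.test`, `aov`, `chisq.test`,
`kruskal.test`) to $10^{-8}$ rather than delegating to the same code it
checks.

The headline inference — do planned-versus-actual deviations exceed the
navigation registration error? — is an ANOVA over {head MADs, tip MADs,
per-case TREs} with Holm–Šidák post-tests of each deviation group against
the TRE group. Two deliberate quirks are preserved and logged:
deviation metrics are per screw while TRE is per case (the conventional
mixing of analysis units; `aggregate_tre_per_case = TRUE` avoids it), and
the angle group is dimensionally incommensurable with millimetre errors,
so it is computed only on request and flagged with a units-mismatch
warning.

Per-level analysis excludes levels with fewer than `min_n = 3` screws from
inference (they are still summarized), generalizing the usual practice of
dropping sparsely instrumented cranial levels. Sample SD ($n-1$) is used
throughout.

## The synthetic cohort generator

The generator defines the study conditions; it is not a tuning dial. Its
defaults are fixed to a routine 27-case lumbosacral cohort:

* **Composition.** Per-screw level mix L1 1.4%, L2 5.7%, L3 17.1%,
  L4 28.6%, L5 31.4%, S1 15.8%; constructs of 1–4 segments with
  probabilities 44.4/37.0/11.1/7.5%; two screws (left/right) per
  instrumented vertebra. Constructs are placed by sampling the caudal-most
  vertebra from weights (L4 0.08, L5 0.48, S1 0.44) jointly calibrated
  with the construct mix so that the realized level frequencies reproduce
  the target mix. Diagnosis, age, weight and height mixes follow the same
  cohort profile.
* **Error chain.** A per-case proper rigid navCT→controlCT offset
  (half-normal rotation angle, default scale 2°, about a uniformly random
  axis; isotropic translation, 10 mm scale — the deviation metrics are
  rigid-invariant, so these scales only exercise the registration
  machinery). Per screw: head execution noise $\varepsilon_h \sim
  \mathcal N(0, \sigma_h^2 I_3)$ and an axis tilt of half-normal magnitude
  $|\mathcal N(0, \sigma_\theta^2)|$ about a uniformly random
  perpendicular axis — the simplest isotropic model consistent with
  reporting angle means ± SD — with the tip placed at
  $\mathrm{head}' + L\,\hat u'$. Reference-screw fiducials (two per
  vertebra on the laminae) carry isotropic localization noise
  $\sigma_{\mathrm{FLE}}$ on both sides of the patient registration;
  per-vertebra verification landmarks (eight vertebral-body corner points)
  carry $\sigma_{\mathrm{coreg}} = 0.3$ mm.
* **Calibration constants** (documented here and in source; chosen once
  from the benchmark magnitudes, never re-fit): $\sigma_h = 3.26$ mm so
  that the chi(3) mean $2\sqrt{2/\pi}\,\sigma_h = 5.20$ mm matches the
  benchmark mean head deviation of 5.2 mm; per-level $\sigma_\theta$ equal
  to benchmark per-level mean angles (4.8–6.4° at L2–L5, 9.3° at S1, 5.5°
  assumed at the sparsely instrumented L1) divided by
  $\sqrt{2/\pi}$, giving an overall mean angular deviation near 6.3° with
  the S1 excess built in as an *emulation* of the reported level effect,
  not ground truth; $\sigma_{\mathrm{FLE}} = 0.55$ mm, calibrated by
  simulation so the mean per-case TRE at the screw heads is ≈0.87 mm.
* **Exclusion mechanism.** Optionally, a cranio-caudal 5 mm shift is
  injected at the cranial-most instrumented level of a chosen number of
  cases (landmarks and final screws of that level move together),
  emulating intersegmental alignment change between the two CTs. A
  cranio-caudal direction is used because a relative shift along the
  stacking axis of two vertebra clusters cannot be absorbed by any rigid
  fit, so the verification residual reliably reveals it.
* **Corridors.** Each pedicle's corridor is centred on the planned screw
  axis with per-level semi-axes (transverse 3.6–8.0 mm growing L1→S1,
  sagittal 6.5–8.0 mm) and an axial extent of 8–28 mm from the entry
  point. These are plausible literature-style pedicle dimensions, not
  measurements; planned screws are grade A by construction.

### What the generator does and does not emulate

It reproduces error *magnitudes*, cohort composition, the registration
chain, and the exclusion mechanism — which is what the pipeline's
correctness tests need. It does not reproduce real anatomy (vertebrae are
a stacked template), surgeon behaviour, or the correlation structure of
in-vivo errors. Two consequences are worth stating plainly:

* With head noise and axis tilt independent, the implied mean tip
  deviation is ≈7.5 mm, larger than the ≈5.5 mm seen in vivo, where head
  and trajectory errors are anticorrelated because the screw pivots in
  the pedicle. Matching all three of head/tip/angle means simultaneously
  would require a correlated error model the benchmark data do not
  constrain; we keep the simple model and let the tip deviation be what
  it implies.
* Under purely isotropic execution noise of this magnitude the geometric
  grading yields many B–D screws, unlike the ≈92% grade A observed
  clinically — real navigation errors are constrained by the pedicle wall
  itself. The grading module is therefore validated against analytic
  geometry, not against a clinical grade distribution.

Passing tests on synthetic cohorts show the pipeline measures what was
injected; they do not certify accuracy claims about any real system.

## Numerical and design choices

* Rigid fits reject fewer than 3 landmark pairs or collinear
  configurations (`navscrew_underdetermined_error`).
* Screw tables validate `|head−tip| ≈ length` (warn above 1 mm, error
  above 5 mm) and reject coincident head/tip points.
* Verification flags strictly above $\tau$ (equality passes).
* Deviations are computed in the controlCT frame after mapping the plan
  with the fitted co-registration; by rigid invariance the direction of
  mapping is irrelevant, but it is fixed for reproducibility.
* Angles are computed with a clamped arccos; at exactly zero deviation the
  arccos is ill-conditioned and values of order $10^{-6}$ degrees are
  numerical zero.
* All randomness flows from a single integer seed in the simulation
  config; identical seeds give bit-identical cohorts and byte-identical
  report files.

## Problem sizes used in validation

The packaged checks run at: $10^5$ screws for the closed-form head-MAD
check (observed agreement ≈0.1%); $10^3$ random configurations for exact
registration recovery and for sampled-versus-analytic breach agreement;
100 random common rigid transforms for invariance at $10^{-9}$;
$10^4$ screws (1800 cases) for end-to-end recovery of
$\sigma_h$ and $\sigma_\theta$ within 5%; $10^4$ null replicates per test
for type-I error 0.05 ± 0.01 and $10^3$ random datasets for
reference-implementation agreement at $10^{-8}$; 100 seeded 27-case
replicates for the deviation-versus-TRE inference; and a 27-case cohort
with three shifted cases for the exclusion mechanism.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_cases = 30, seed = 1,
                         per_level_shift_mm = 5, n_shift_cases = 3)
report <- run_pipeline(pipeline_config(cohort = simulate_cohort(cfg)))
print(report)
report$deviation_vs_tre$posthoc
```

## Known limitations

Beyond the generator limitations above: the corridor is a straight
elliptical cylinder (real pedicles narrow at the isthmus and curve); the
grading surrogate has no reader variability; landmark-based
co-registration is a stand-in for intensity-based image registration and
its residuals are not the same quantity a visual verification judges; and
no DICOM/volume handling is provided or planned.
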