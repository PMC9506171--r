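# navscrew

Three-dimensional planned-versus-actual accuracy analysis for CT-navigated
pedicle screw placement.

## What this is for

In navigated spinal instrumentation each pedicle screw is planned as a
virtual trajectory (head point, tip point, length, diameter) on an
intraoperative CT, and the implanted screw is later segmented on a
postoperative control CT. Categorical grading of the final screw position
(Gertzbein–Robbins) answers "is the screw safe?", but not "how faithfully
was the plan executed?". `navscrew` is for surgeons, medical-image
scientists and navigation engineers who want the second question answered
quantitatively and reproducibly:

- **Geometry** — frame-tagged 3D points, unit directions and proper rigid
  transforms; mixing un-coregistered frames is a hard error.
- **Registration** — landmark-based least-squares rigid fits (SVD with
  reflection correction), FRE at the fiducials, TRE as the *mean* distance
  at held-out targets, and a per-level co-registration verification rule
  with case-level exclusion (threshold τ = 2 mm by default).
- **Deviation** — per screw, after mapping the plan into the control
  frame: head and tip point deviations `MAD = sqrt(dx² + dy² + dz²)` (mm),
  angular deviation of the head→tip axes `θ = arccos(û_p · û_f)`
  (degrees), and length/diameter differences; per-level summaries with a
  minimum-n rule.
- **Grading** — a computable Gertzbein–Robbins surrogate: maximum breach
  of the screw cylinder outside an elliptical pedicle corridor, graded
  A (≤0 mm), B (<2), C ([2,4)), D ([4,6)), E (≥6); A–B acceptable.
- **Statistics** — pooled/Welch t, one-way ANOVA with Holm–Šidák
  step-down post-tests, Pearson χ², Kruskal–Wallis; and the headline
  comparison of screw deviations against the navigation registration
  error.
- **Synthetic cohorts** — a seeded generator of full study cohorts
  (screws, corridors, fiducials, verification landmarks, covariates) with
  ground truth retained, calibrated so its long-run means sit at the
  accuracy benchmarks for routine lumbosacral navigation (head deviation
  5.2 mm, angle 6.3°, registration error 0.87 mm).

## Worked example

```r
library(navscrew)

cfg <- simulation_config(n_cases = 30, seed = 1,
                         per_level_shift_mm = 5, n_shift_cases = 3)
report <- run_pipeline(pipeline_config(cohort = simulate_cohort(cfg)))
print(report)
```

```
[verify] excluded 3 case(s) for inaccurate co-registration: C0004, C0009, C0023
== planned-versus-actual screw accuracy report ==
cases: 27 analyzed / 30 input (3 excluded); screws: 148
  mad_head_mm   5.18 +/- 2.16 mm (range 0.60-11.29)
  mad_tip_mm    8.03 +/- 3.95 mm (range 2.02-25.67)
  angle_deg     6.84 +/- 5.60 deg (range 0.10-32.05)
  registration error: 0.86 +/- 0.37 mm (n=27 cases)
  grades: A=26 B=41 C=45 D=20 E=16
```

Reading this: three cases were dropped because the injected 5 mm cranial
intersegmental shift broke rigid co-registration at their cranial level
(exactly the three shifted cases). Across the remaining 148 screws the
implanted positions deviate from their plans by ~5 mm at the head and ~7°
in direction — an order of magnitude above the 0.86 mm navigation
registration error, which the post-hoc test confirms:

```r
report$deviation_vs_tre$posthoc
#>                       comparison        p_raw p_adjusted
#> 1 head_mad vs registration_error 7.565294e-20          0
#> 2  tip_mad vs registration_error 3.147239e-17          0
```

The synthetic tip deviation and grade distribution are deliberately what
the independent-error model implies (see the methods vignette,
`vignettes/screw-accuracy-methods.Rmd`, for why they differ from in-vivo
cohorts).

A thin CLI wrapper ships in `inst/scripts/navscrew-cli.R`
(`simulate` / `run` subcommands).

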