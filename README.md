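# torsionrig

Cyclic torsion analysis for physeal fracture fixation constructs.

`torsionrig` implements the biomechanical analysis used to compare
Kirschner-wire fixation strategies (three vs two vs one pin) for
Salter-Harris type I fractures of the proximal humeral physis under cyclic
torsional loading (±2 Nm, 0.5 Hz, 250 cycles, 20 N axial preload). It is
aimed at orthopaedic biomechanics groups who need a tested, reusable version
of the three estimators such studies rely on, plus a synthetic test rig so
the whole pipeline can be exercised without access to raw laboratory
records.

## What it computes

For each loading cycle of a torque–angle record:

* **Torsional stiffness** *k* (Nm/°) — the gradient of the linear terminal
  limb of the sigmoidal load–displacement curve, selected by the iterative
  rule: anchor at the torque extremum, start from 10 points, grow/shrink the
  contiguous window while the torque-on-angle regression keeps
  *R*² ≥ 0.995.
* **Toggle** τ (°) — interfragmentary free play around zero load, the gap
  between the x-intercepts of the external and internal terminal lines:
  τ = θ₀⁺ − θ₀⁻.
* **Gross angular displacement** (°) — full-cycle peak-to-peak rotation,
  max θ − min θ, from the machine record and, via the Law of Cosines on
  axis-projected marker positions,
  φ = arccos[(r₁² + r₂² − d²)/(2 r₁ r₂)], from motion-capture markers.

Group comparison follows the linear mixed-effects formulation
`y ~ pin_group + cycle + (1 | specimen) [+ (1 | marker)]` (ML fits,
likelihood-ratio p-values, paired follow-up t-tests), and the synthetic rig
simulates the full repeated-measures study: sigmoidal backbone
θ(T) = T/k + (τ/2)·tanh(T/T₀), per-aspect marker rotation shares and
actuator–bone slippage.

## Worked example

Simulate one construct at the two-pin group level, then recover its
parameters:

```r
library(torsionrig)

protocol <- load_protocol()                      # +/-2 Nm, 0.5 Hz, 250 cycles, 1000 Hz
params   <- construct_params(stiffness_true = 1.10, toggle_true = 5.08,
                             pin_group = "two")  # angle noise 0.02 deg
trace    <- generate_trace(protocol, params, seed = 42)

analyze_trace(trace)                             # cycles 60, 120, 180
#>   cycle gross_mts stiffness toggle_total n_points_external n_points_internal
#> 1    60      8.82      1.04         4.91                12                12
#> 2   120      8.79      1.04         4.91                12                12
#> 3   180      8.78      1.04         4.91                12                12
#> # (plus per-branch stiffness and signed toggle columns)
```

The recovered stiffness (1.04 Nm/°) and total toggle (4.91°) sit within a
few percent of the construct's true 1.10 and 5.08 — the small downward pull
is the terminal-window contamination discussed in the methods vignette —
and `gross_mts` ≈ 2·(2/1.10) + 5.08 ≈ 8.7° is the closed-form peak-to-peak
response. A full study — 12 specimens × 3 pin groups with marker tracking,
group summaries, mixed models and the machine-vs-motion comparison — is one
call:

```r
report <- run_pipeline(pipeline_config(seed = 1))
report
#> <torsion_report>
#>   stiffness    three: 1.14 +/- 0.22  two: 1.10 +/- 0.20  one: 1.10 +/- 0.30
#>   toggle       three: 4.45 +/- 0.94  two: 4.97 +/- 1.14  one: 6.18 +/- 2.25
#>   gross_mts    three: 8.15 +/- 1.36  two: 8.81 +/- 1.40  one: 10.12 +/- 2.31
#>   gross_motion three: 3.18 +/- 1.01  two: 3.42 +/- 1.04  one: 3.88 +/- 1.38
#>   MTS / motion displacement ratio: 2.58 (p = 1.17e-57)
write_report(report, "report.json")
```

The one-pin group shows the largest toggle and gross displacement while
stiffness stays flat across groups, and the machine reports ~2.6× the
marker-tracked rotation (mould–bone slippage) — the qualitative fingerprint
of the reference experiment. Derived arithmetic helpers reproduce its
printed comparisons exactly:

```r
ratio_and_percent(4.22, 2.75, "ratio")                       # 1.53x one vs two pins
ratio_and_percent(2.75, 2.34, "percent_decrease_of_larger")  # 14.91 % increase
implant_area_fraction(3, 3.0, 30)$fraction                   # 3 % of the physis
```

A thin command-line driver wraps the same functions
(`inst/scripts/torsionrig.R simulate|analyze|report|all`).

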