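# wallmech

Tensile mechanics of plant epidermal cell walls as a fibrous network.

Growing plant cells stretch their walls far beyond the small-strain
regime, and stretched leaf epidermis shows a J-shaped response with
three regimes: a soft plateau (tangent stiffness ~12 N/m), a
strain-stiffening rise, and a stiff plateau (~70 N/m), accompanied by a
nonmonotonic incremental Poisson's ratio that exceeds 1 at its peak and
by recovery that falls from above 80% to about 40% under incremental
cyclic loading. `wallmech` implements the complete analysis pipeline
for such tests and the mechanistic models that interpret them, for
plant biomechanists and anyone working with J-shaped soft-network
tensile data.

Core quantities, in the field's notation: axial stretch
λ_ax (deformed/initial length), transverse stretch λ_tr, membrane force
(force per initial width, N/m), tangent stiffness k = d(f)/dλ_ax,
incremental Poisson's ratio ν_inc = −dln λ_tr/dln λ_ax, and the regime
metrics E1, E2 (mean k over stretch 1.02–1.05 and over the final
plateau), ν1, ν2 (mean ν_inc over 1.02–1.05 and over ±0.05 stretch
around its peak).

What's inside:

* **Tensile analysis** — smoothing-spline curve conditioning under the
  protocol's R² > 0.999 constraint, tangent stiffness and ν_inc from
  the fitted derivatives, three-regime summary extraction, cycle
  segmentation, per-cycle recovery and residual-stretch-versus-force
  tables (`smooth_curve`, `derive_curves`, `extract_summary`,
  `split_cycles`, `recovery_analysis`).
* **Five-beam unit** — the diamond of four stretching beams and one
  bending transverse beam with elastoplastic connector slip
  (1D return mapping), quasi-static monotonic and cyclic simulation,
  and parameter sweeps (`five_beam_params`, `simulate_monotonic`,
  `simulate_cyclic`, `parameter_sweep`). With defaults it reproduces
  the three-regime phenomenology, the interior ν_inc maximum, and the
  recovery decline.
* **Affine isotropic network** — the rejected null mechanism: affinely
  convected fibers, uniform orientations, uniaxial response by zero
  transverse membrane force (`affine_params`, `uniaxial_response`).
  Two regimes only; ν_inc monotone; small-strain ν = 1/3.
* **Continuum references** — compressible neo-Hookean / Yeoh
  plane-stress plate, thin-shell inflation with limit-point detection,
  and the pressurized-cylinder Poisson-stiffening argument
  (`hyperelastic_material`, `plane_stress_uniaxial`, `inflate_shell`,
  `cylinder_axial_response`).
* **Synthetic data** — a seeded generator that emulates the measured
  phenomenology with ground truth attached, so the whole pipeline is
  testable without experimental data (`generator_profile`,
  `generate_monotonic`, `generate_cyclic`, `generate_from_model`).
* **I/O** — the curve CSV dialect
  (`time_s,lambda_ax,lambda_tr,force_per_width_N_per_m[,segment]`),
  summary JSON, and validated run configurations (`read_curve_csv`,
  `write_outputs`, `read_run_config`).

## Worked example

Generate a synthetic monotonic test at the measured tissue calibration
and analyze it end to end:

```r
library(wallmech)
g <- generate_monotonic(generator_profile(seed = 101))
s <- extract_summary(derive_curves(g$curve))
print(s)
#> Tensile summary (three-regime extraction)
#>   E1  =   11.924 N/m   (initial stiffness, stretch 1.02-1.05)
#>   E2  =   70.014 N/m   (final stiffness plateau)
#>   nu1 =    0.300       (initial incremental Poisson's ratio)
#>   nu2 =    1.010       (peak incremental Poisson's ratio at 1.203)
#>   regimes: I ends 1.119, III starts 1.262, max stretch 1.500
```

The recovered metrics sit within a fraction of a percent of the
generator's ground truth (E1 = 12, E2 = 70 N/m, ν1 = 0.3, peak ν above
1) despite the seeded measurement noise. The five-beam unit produces
the same phenomenology from mechanism rather than construction:

```r
cur <- simulate_monotonic(five_beam_params())
print(extract_summary(as_derived_curves(cur)))
#> Tensile summary (three-regime extraction)
#>   E1  =    6.341 N/m   (initial stiffness, stretch 1.02-1.05)
#>   E2  =   21.943 N/m   (final stiffness plateau)
#>   nu1 =    0.845       (initial incremental Poisson's ratio)
#>   nu2 =    1.322       (peak incremental Poisson's ratio at 1.272)
#>   regimes: I ends 1.077, III starts 1.343, max stretch 1.500
```

Model units are arbitrary — the unit reproduces trends, not
magnitudes: a 3.5-fold stiffening between flat regimes, an interior
Poisson-ratio peak above 1, and (under `simulate_cyclic`) recovery
declining from 100% toward a plateau near 84%.

The `analysis/` directory holds the numbered workflow drivers —
`01_generate_synthetic.R` through `05_pressurized_shells.R` — which
generate the data set, run the pipeline, contrast the three models,
sweep connector resistance and beam angle, and run the pressurized
shell analyses, writing their tables under `results/`.

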