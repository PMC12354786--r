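---
title: "Fibrous-network mechanics of stretched plant epidermal cell walls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibrous-network mechanics of stretched plant epidermal cell walls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallmech)
```

## The measurement and its derived quantities

When a strip of leaf epidermis is stretched on a tensile stage, three
series are recorded against time: the axial stretch
$\lambda_{ax}$ (deformed length over initial length), the transverse
stretch $\lambda_{tr}$ (deformed width over initial width), and the
membrane force — force divided by the *initial* strip width, in N/m.
Stretches are used rather than strains because the deformations are
large (up to 50% extension before failure).

Growing epidermal tissue shows a characteristic J-shaped response with
three regimes: a soft initial regime (I) with a nearly constant tangent
stiffness around 12 N/m, a strain-stiffening regime (II), and a stiff
final regime (III) with a nearly constant stiffness around 70 N/m.
Four scalar metrics summarize a test:

* `E1`, the initial stiffness — the tangent stiffness (slope of force
  per width versus axial stretch) averaged over the stretch window
  1.02–1.05;
* `E2`, the final stiffness — the tangent stiffness averaged from the
  stretch where its derivative first approaches zero up to the maximum
  stretch minus 0.05;
* `nu1`, the initial incremental Poisson's ratio, averaged over
  1.02–1.05;
* `nu2`, the peak incremental Poisson's ratio, averaged over a window
  of ±0.05 stretch around its maximum.

The incremental Poisson's ratio is the negative ratio of increments of
the natural logarithms of the two stretches,
$\nu_{inc} = -\,d\ln\lambda_{tr}/d\ln\lambda_{ax}$. Two identities
anchor its interpretation: $\nu_{inc}=1$ on any path with
$\lambda_{tr} = 1/\lambda_{ax}$ (surface area conserved), and
$\nu_{inc}=0.5$ on the incompressible-uniaxial path
$\lambda_{tr} = \lambda_{ax}^{-1/2}$ typical of rubbery solids. The
measured tissue crosses 1 during regime II — it loses surface area
while stretching — and then passes an interior maximum, which classical
soft materials never do.

In incremental cyclic tests, the sample is repeatedly loaded to an
increasing peak and unloaded to zero force. The recovery percentage of
a cycle is the recovered deformation relative to the total deformation,
$100(\lambda_{peak}-\lambda_{res})/(\lambda_{peak}-1)$, where
$\lambda_{res}$ is the stretch at the zero-force crossing of the
unloading branch. Transverse recovery is defined symmetrically with
$1-\lambda_{tr}$ as the deformation measure.

## Curve conditioning

All derived quantities come from smoothing-spline fits, never from
finite differences of raw samples — differentiation amplifies noise and
the protocol's load-cell and image-correlation channels both carry
some. The fits must reproduce the samples with a coefficient of
determination above 0.999, matching the fit quality the tensile
protocol reports.

`smooth_curve()` selects the smoothing level by generalized
cross-validation and then *enforces* the $R^2$ floor, backing the
smoothing off by bisection when the GCV choice is below it. We also
expose a `max-smooth` rule (the largest smoothing parameter whose fit
still clears the floor). GCV is the default because the floor alone is
a weak constraint on derivatives: a fit at exactly $R^2 = 0.999$ on a
noise-free three-regime curve flattens the stiffening ramp enough to
corrupt `E2` by tens of percent, while GCV approaches interpolation on
clean data and reproduces the generator's tangent curves essentially
exactly. If no smoothing level reaches the floor the fit aborts with
the best achievable $R^2$ — this happens when measurement noise is
large relative to the signal, in which case the protocol's reported fit
quality could not have been achieved either.

## Extraction conventions

The summary rules leave two operational gaps that `extract_summary()`
must close.

*Where does the final plateau start?* "The derivative of the stiffness
first approaches zero" is made scale-free: the plateau begins at the
first grid stretch where $|dk/d\lambda|$ falls below `plateau_frac`
(default 0.05) times the stiffness range over the stretch range, *or*
where $dk/d\lambda$ changes sign — a local extremum means the
derivative passed through zero between grid points, and accepting the
sign change makes the rule independent of grid resolution. The search
starts after regime I ends (first stretch at or beyond 1.05 where the
stiffness exceeds 1.2 `E1`), because model curves can dip slightly
within regime I and a search from the origin would lock onto that dip.

*Where does the unloading branch cross zero force?* Samples below 0.5%
of the cycle's peak force count as zero. Detection runs on a short
centered running mean of the force so that additive noise cannot
trigger it early, with raw samples accepted in the final window (the
running mean is biased upward where a branch terminates exactly at
zero); the residual stretch is then solved from a local least-squares
line through the raw samples around the detected crossing. On
noise-free piecewise-linear branches this reduces to exact linear
interpolation.

Window averages use trapezoidal quadrature with interpolated window
edges, which makes the summary invariant to resampling density (the
suite checks better than 0.5% on doubling the grid).

## The five-beam unit

The central mechanistic model is a diamond of four stretching beams
(AC, AD, BC, BD) joined to one transverse beam (AB), a conceptual unit
for the cellulose microfibril network of the primary wall: most
microfibrils rotate toward the loading direction and elongate
elastically, microfibrils near the transverse direction bend, and
fiber–fiber connections (matrix-mediated or direct cellulose–cellulose
contacts) transfer force between them, deforming elastically and
slipping plastically above a force threshold. Loading nodes C, D sit on
the axial axis at $\pm s$; transverse nodes A, B sit at
$\pm s\tan(\theta/2)$ so the angle between the stretching beams meeting
at a loading node equals $\theta$. Mirror symmetry about both axes
reduces the quasi-static problem to a single geometric unknown (the
transverse half-span) plus the connector's internal slip variable,
solved by bracketed root finding with an elastoplastic return map per
increment; converged residuals are below $10^{-10} k_s$ and the
response is increment-size independent to $10^{-6}$.

**Connectors.** One elastoplastic element acts in series with each
stretching beam. The return map is the standard one-dimensional
rate-independent construction: elastic below the current yield force
`f_slip + H * slip`, otherwise the force returns to the hardening yield
surface and the excess becomes slip. A strictly positive hardening
modulus `H` is the default: with perfect plasticity the post-yield
tangent of the unit collapses, so regime III could not be a stiff
plateau while slip accumulates — incompatible with the observed
response, where stiffening beyond the previous maximum load continues
as in monotonic tests. Physically, `H > 0` corresponds to the breaking
and re-forming of fiber–fiber contacts rather than their loss.

**Bending law.** The transverse beam's compressive force versus end
shortening has three parts: a pre-critical branch
$P = P_{cr}\,u(1+u^m)^{-1/m}$ (initial stiffness
$k_0 = P_{cr}/(\texttt{bend\_rise\_frac}\,L_{AB})$, saturating at the
post-buckling plateau $P_{cr}$ with knee sharpness $m$), an optional
linear hardening term, and a convex compaction term
$P_{cr}\,h\,w^2/(1-w/w_{wall})$ that diverges as the chord closes. The
convex term is what arrests the transverse collapse and turns the
incremental Poisson's ratio over; a purely linear hardening cannot be
simultaneously soft enough early (to let $\nu_{inc}$ rise) and stiff
enough late (to stop the collapse), which we verified by parameter
scans before adopting the convex form. Negative shortening is treated
as straight-beam extension.

**Defaults.** The unit is deliberately not calibrated to tissue force
magnitudes; its job is qualitative. The shipped defaults
(`k_s = 35`, `k_c = 300`, `bend_Pcr = 1`, `bend_harden = 13`,
`f_slip = 2.5`, `H = 60`, $\theta_0 = 90^\circ$) were chosen, once, so
that the unit reproduces the experimental trends: a soft regime-I
plateau (stiffness within ±10% of its mean over the `E1` window), a
monotone stiffening rise, a final plateau within ±10%, an interior
maximum of $\nu_{inc}$ followed by a decline, recovery decreasing with
peak stretch and leveling off, and a cyclic envelope that rejoins the
monotonic curve. Two structural facts fix where the defaults live.
First, the initial stiffness is the series combination of twice the
bending stiffness and the beam–connector chain, so the observed
*insensitivity of `E1` to connector resistance* requires the
stretching-beam compliance to dominate that chain
($k_s/L_0 \ll k_c$) — with the connector dominant, `E1` would track
`k_c`. Second, the slip threshold is placed mid-rise so the plastic
tangent, not an elastic overshoot, forms the regime-III plateau; this
also makes the recovery decline start inside regime II, as observed.

**Anisotropy sweep.** Preferential microfibril alignment is modeled by
perturbing $\theta$. The unit's `E1` is strongly geometry-sensitive
(about 5% per degree at the defaults — the model's known
oversensitivity of initial quantities to geometry), so the sweep uses
$\theta_1 = 88^\circ$ and $\theta_2 = 92^\circ$: the largest
perturbation at which "similar `E1` (within 10%)" can hold, while the
`E2` and Poisson-ratio contrasts remain strictly ordered and an order
of magnitude above solver noise.

## The affine network null model

The alternative hypothesis — that microfibril reorientation under an
affine deformation assumption explains the nonlinearity — is
implemented as an isotropic planar fiber network: fibers uniformly
distributed in orientation, each stretched to
$\lambda_f = \sqrt{\lambda_{ax}^2\cos^2\theta_0 +
\lambda_{tr}^2\sin^2\theta_0}$, with membrane forces from the
orientation average (midpoint quadrature, 360 nodes by default;
isotropy error below $10^{-6}$) and the transverse stretch solved from
zero transverse membrane force. The default fiber law is Green-strain
(St. Venant–Kirchhoff), $t_f = \kappa_f\lambda_f(\lambda_f^2-1)/2$; a
law linear in stretch is available. Both share the tangent $\kappa_f$
at $\lambda_f = 1$, so the small-strain network Poisson's ratio is 1/3
either way (the classical affine value in 2D), but the linear law
stiffens only a few percent between stretches 1.02 and 1.10, too weak
to exhibit the "no initial plateau" behavior that distinguishes this
model class from the data; the Green-strain default rises about 24%
over the same window. Either way the model fails in the same
diagnostic direction: only two regimes, and a monotonically increasing
incremental Poisson's ratio with no interior maximum — which is the
point of keeping it.

## Plate and shell references

The homogeneous plane-stress plate isolates what a continuum membrane
can and cannot do. Materials follow the deviatoric/volumetric split
$W = \sum_i C_{i0}(\bar I_1 - 3)^i + (1/D_1)(J-1)^2$ so published
constants carry over; for neo-Hookean, $C_{10} = \mu/2$ and
$D_1 = 2/K$. The normalized plate uses $\mu = 5/13$, $K = 5/6$, i.e.
unit small-strain modulus and Poisson's ratio 0.3. Plane stress is
enforced by a scalar root find on the transverse stretch (for an
isotropic material under uniaxial tension the transverse and
through-thickness stretches coincide) with tolerance $10^{-14}$; the
incompressible closed form $\mu(\lambda - \lambda^{-2})$ is recovered
to 0.5% at $K/\mu = 10^4$, and the returned state's stored energy
matches the work integral of the force–stretch curve to 0.1%. The
plate's response is smooth and convex — no initial plateau, no
three-regime structure — so the tissue's nonlinearity is not a
continuum-plate artifact.

Two side analyses use thin pressurized shells. Inflation solves the
Laplace relation with current geometry; a linear-elastic spherical wall
(with incompressible thinning $t = t_0/\lambda^2$) has the closed-form
limit point at $\lambda = 3/2$, beyond which slight pressure increases
produce runaway stretch, while a wall carrying the measured 12→70 N/m
stiffness profile remains single-valued far beyond it — the mechanical
argument for why strain stiffening protects turgid cells. The
pressurized-cylinder response uses first-order wall kinematics with the
pressure cap force on the current radius, the minimal formulation in
which the wall's Poisson ratio enters: radius contraction under axial
stretch reduces the cap force, giving an effective stiffness
$\approx 2\pi r_0 t E(1 + \nu\,p r_0/(tE))$, monotone in $\nu$. This
formulation is deliberately provisional — it pins the trend, not a
finite-deformation theory — and is valid where the hoop strain is
small.

## The synthetic-data generator

`generator_profile()` encodes the study conditions the analysis is
meant to face: a three-regime stiffness profile with plateaus at 12 and
70 N/m (the measured tissue values), a cubic-smoothstep ramp between
stretches 1.10 and 1.25 (generator conventions, chosen $C^1$ so spline
derivative checks are clean), a compactly supported quartic bump
carrying the incremental Poisson's ratio from 0.3 to a peak of 1.1 at
stretch 1.20 (support chosen to leave the 1.02–1.05 window untouched),
and a recovery schedule interpolating 85% → 40% across the ramp —
mirroring the observed decline from above 80% to about 40% with a
plateau. Loading follows the envelope; unloading descends a straight
chord to the scheduled residual. Noise is additive Gaussian,
independent per sample, on the measured channels only (force and
transverse stretch; axial stretch is the controlled variable), with
defaults 0.05 N/m and $10^{-3}$ — the scale consistent with the
protocol's reported smoothing fit quality, since much larger noise
makes an $R^2 > 0.999$ spline unattainable on this signal. Each
generated set carries machine-readable ground truth; the expected
summary metrics are window averages of the true profiles under the same
extraction conventions, which is the correct oracle for a round-trip
test.

What passing round trips do *not* show: the generator has no
viscoelasticity (the measured loading–unloading hysteresis beyond
plasticity is absent by design), no image-correlation artifacts, no
across-specimen biological variability, and its regime boundaries are
sharp conventions rather than gradual biological transitions. Green
tests certify the pipeline's correctness on data obeying the stated
model, not the model's truth on tissue.

## Problem sizes and runtimes

Model curves use 201-point stretch grids over [1, 1.5] with internal
increments of at most 0.0025; synthetic curves use 500 samples; cyclic
protocols use peaks every 0.05 stretch up to 1.7. These sizes put all
discretization errors well below the tolerances asserted in the test
suite while keeping any single simulation below a few seconds.

## Known limitations

* The five-beam unit is a single cell of an irregular multilamellate
  network; magnitudes are not comparable to tissue values, and initial
  quantities (`E1`, `nu1`) are oversensitive to the unit's geometry.
* Only plastic slip is modeled; the viscous component of the measured
  hysteresis is out of scope.
* The cylinder coupling is first-order and trend-level pending a full
  finite-deformation treatment.
* The affine model's fiber law beyond its small-strain tangent is a
  modeling choice; both shipped laws reproduce the same qualitative
  mismatch with the data.
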