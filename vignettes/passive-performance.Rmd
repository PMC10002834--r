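---
title: "Passive performance of a cavopulmonary assist device: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive performance of a cavopulmonary assist device: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Patients palliated with a Fontan total cavopulmonary connection (TCPC) have
no subpulmonary ventricle: both venae cavae drain directly into the
pulmonary arteries.  Rotary cavopulmonary assist devices placed in the
junction can restore a modest (5–7 mmHg) subpulmonary pressure rise, but
because the device sits **in series** with the entire venous return, its
behavior when *stopped* (0 RPM) is a first-order safety question: a
resting-state obstruction of 2 mmHg or more across a Fontan pathway is
clinically significant.  `fontanflow` implements a desk-scale computational
replica of the passive (failed-pump) evaluation pipeline for such a device:
an idealized four-port junction housing, with and without a static
biconical pump insert, is meshed, solved, and scored on pressure loss,
caval flow split, power loss, shear-based thrombosis surrogates and
virtual-dye washout, with Bland–Altman statistics against (synthetic)
mock-circulatory-loop measurements.

Everything is generated in code; there are no external data dependencies.

## Flow model

Incompressible Newtonian flow in a rigid domain $\Omega$:

$$\int_\Omega \mathbf{w}\cdot(\rho\mathbf{v}_{,t} +
\rho\mathbf{v}\cdot\nabla\mathbf{v} - \mathbf{f})\,d\Omega
+ \int_\Omega \nabla\mathbf{w} : (-p\mathbf{I} + \boldsymbol\tau)\,d\Omega
- \int_{\Gamma_h} \mathbf{w}\cdot\mathbf{h}\,d\Gamma
+ \int_\Omega q\,\nabla\cdot\mathbf{v}\,d\Omega = 0,$$

with $\boldsymbol\tau = \mu(\nabla\mathbf{v} + \nabla\mathbf{v}^T)$, no-slip
rigid walls, parabolic inlet velocity profiles scaled so the *discrete*
inlet flux equals the prescribed flow exactly, and resistance outlets
$\mathbf{h} = -R\,Q\,\mathbf{n}$ where $Q = \int_{\Gamma}\mathbf{v}\cdot
\mathbf{n}\,d\Gamma$ is the instantaneous outlet flux of the current
iterate (implicit rank-one coupling).  Units are CGS throughout; pressures
are reported in mmHg with 1 mmHg = 1333.22 dyn/cm².

The discretization is equal-order linear simplices (P1–P1) with
residual-based stabilization: SUPG/PSPG with

$$\tau_m = \left(\tfrac{4}{\Delta t^2} + \mathbf{v}\cdot\mathbf{G}\mathbf{v}
+ C_I \nu^2 \mathbf{G}:\mathbf{G}\right)^{-1/2},\qquad C_I = 36,$$

where $\mathbf{G}$ is the element covariant metric, plus a grad-div term
with kinematic coefficient $\nu_{LSIC} = (\tau_m\,\mathrm{tr}\,\mathbf{G})^{-1}$
(the $h^2/\tau_m$ scaling appropriate to linear simplices).  In steady
mode the $4/\Delta t^2$ term is dropped: the stabilization must remain purely
spatial or the pressure field degenerates as the pseudo-step shrinks.
Backflow stabilization adds the convective-inflow penalty
$-\beta\rho(\mathbf{v}\cdot\mathbf{n})_-\,\mathbf{v}$ on outlet faces with
locally reversed flow, $\beta = 0.2$ by default (the conventional value;
only the technique, not the coefficient, is standard in the source
literature).

**Time integration** is the second-order generalized-$\alpha$ method for
first-order systems with $\rho_\infty = 0.5$ by default, Newton–Raphson
correction each step (relative tolerance $10^{-3}$, at most 6 corrections).

**Steady mode** is pseudo-transient continuation, used for the whole
acceptance-profile study because the bench protocol's 5 s transients at
$\Delta t = 1$ ms are out of scale for a single desk CPU.  Three features
proved necessary and are worth recording:

1. *Viscosity continuation.*  The solve walks down a ladder of elevated
   viscosities (16×, 4×, 1×), each stage warm-starting the next, so the
   advection-dominated final stage starts near its solution.
2. *Floored SER damping.*  Each pseudo-step is a linearized backward-Euler
   step with lumped-mass damping $\rho M/\Delta\tau$; $\Delta\tau$ grows
   when the steady residual falls and is floored so the state always moves.
3. *A full-Newton push.*  Near the root the controller forces
   $\Delta\tau \to \infty$.  Quasi-steady junction states at higher cardiac
   output are *linearly unstable* (incipient vortex shedding in the bulged
   housing): damped pseudo-stepping then diverges slowly — the
   amplification per step is $1/(1+\lambda\Delta\tau) > 1$ for an unstable
   eigenvalue $\lambda < 0$ — whereas full Newton contracts onto the root.
   For the same reason the Jacobian must include the SUPG weight-advection
   derivative $\tau_m(\delta\mathbf{v}\cdot\nabla\mathbf{w})\cdot
   \mathbf{r}_m$, which does not vanish at the discrete solution.

When no steady state is reached within the step budget the field is
returned flagged `unsteady_physics` rather than silently averaged; the
bench-replication transient remains available via `solve_transient()`.

## Geometry and meshes

The test-section class is a planar cross junction: two perpendicular
1.91 cm tubes meeting in a spherically bulged housing (maximum diameter
3.4 cm), ports 5 cm from the center so that the 4 cm pressure cut planes
sit inside the arms.  The proprietary pump CAD is not available (only its
blade heights, 1.09 and 1.62 mm, are public), so the static insert is an
*idealized* bicone — two cones base-to-base at the equator, axis normal to
the junction plane — with the blade represented as an annular equatorial
ridge of the given height and four cylindrical support struts in the
junction plane.  This captures the flow blockage and the shear-bearing
surfaces without the proprietary shape.  The thin-film secondary flow path
of the real device is not modeled (its dimensions are never published);
dye trapped against walls appears in the censored fraction of the washout
field instead.

Meshing is native: pipes are structured extruded-cylinder meshes with
optional geometrically graded boundary layers (ratio 1/2 per layer, the
intended reading of the garbled printed rule), and the junction is meshed
on a Cartesian background grid split into Kuhn simplices, keeping cells
whose centroid — or all but one of whose vertices — lies inside the signed
distance field, then projecting boundary nodes onto the zero level set with
an inverted-element safeguard.  The permissive keep rule is what allows
very coarse nested levels (h ≈ 0.9 cm) to retain all four ports; its cost
is a tail of low-dihedral-angle slivers near the surface, which the
stabilized solver tolerates and the mesh audits (positive volumes,
watertightness, single labels) still pass.  A planar (2D) cross-channel
analog of the junction is provided for cheap verification; every operator
is dimension-agnostic.  In 2D the insert is a fitted disk, since the true
equatorial section would seal the planar channel.

## Operating points

The mock-loop operating points are built in: cardiac outputs
{3, 5, 7, 9, 11} L/min, caval split 60/40 (IVC/SVC), blood-analog fluid
$\rho = 1.06$ g/cm³, $\mu = 0.035$ P, and outlet resistances 204.51 (RPA)
and 222.49 (LPA) dyn·s/cm⁵ — the values calibrated on the blank housing at
CO = 11 to give the measured R52/L48 split.  The loop's pulmonary pressure
relations 6.0 + 0.74·CO and 6.0 + 0.77·CO mmHg are exposed for reference.
The inlet Reynolds number helper implements $4\rho Q/(\pi D\mu)$ exactly;
note that the printed Reynolds values in the source study (674 … 2250) are
not reproducible from its own printed fluid properties and split (the
closed form gives 606 … 2221), so the formula, not the printed list, is
authoritative here.

## Endpoints

* **Wall traction**: $\boldsymbol\sigma = -p\mathbf{I} +
  \mu(\nabla\mathbf{v}+\nabla\mathbf{v}^T)$ with nodal velocity gradients
  recovered by volume-weighted element-gradient averaging; the traction is
  projected onto the wall tangent plane at each node,
  $\boldsymbol\tau = \boldsymbol\sigma\mathbf{n} -
  (\boldsymbol\sigma\mathbf{n}\cdot\mathbf{n})\mathbf{n}$, so nodal
  tangency is exact by construction.
* **TAWSS** is the magnitude of the *vector* time average of
  $\boldsymbol\tau$ (average first, then magnitude); **OSI** is
  $\tfrac12(1 - |\int\boldsymbol\tau\,dt| / \int|\boldsymbol\tau|\,dt)
  \in [0, 0.5]$, defined as 0 where the denominator vanishes.  For steady
  solves OSI is identically zero, consistent with the near-zero OSI the
  bench study reports at CO ≤ 5 L/min.  The averaging window defaults to
  t ∈ [2, 5] s for transients (the study's window; whether its OSI used
  the same window is unstated — assumed yes) and to the single snapshot
  for steady runs.
* **Low-WSS area fraction** uses the conventional TAWSS < 5 dyn/cm²
  cutoff, area-weighted by face and monotone in the threshold.
* **Cut-plane pressures** are area-weighted means of the linearly
  interpolated pressure over exact mesh–plane intersections at 4 cm from
  the junction center (planes falling exactly on a node plane are nudged
  by an epsilon); the pressure loss is the inlet-plane minus outlet-plane
  mean and `dP_max` the maximum over the four inlet–outlet pairs.
* **Power loss** is the net static-plus-dynamic pressure flux
  $\sum_{\text{ports}} -\int (p + \tfrac12\rho|\mathbf{v}|^2)
  (\mathbf{v}\cdot\mathbf{n})\,d\Gamma$ in mW — the standard Fontan
  energy-loss definition; the source study never prints its formula, so
  this choice is flagged here.

## Dye washout

Virtual dye obeys stabilized advection–diffusion on the frozen (steady) or
time-interpolated velocity, one-way coupled.  The printed transport
equation carries a spurious $\rho$ on the advective term that is
dimensionally inconsistent for a concentration field; the standard form
$\phi_{,t} + \mathbf{v}\cdot\nabla\phi = \nabla\cdot\kappa\nabla\phi$ is
implemented.  Stabilization uses the printed scalar
$\tau_m = (4/\Delta t^2 + \mathbf{v}\cdot\mathbf{G}\mathbf{v} +
3(\kappa+\kappa_{DC})^2\mathbf{G}:\mathbf{G})^{-1/2}$ and a
discontinuity-capturing diffusivity
$\kappa_{DC} = |\mathcal{L}\phi| / (2\sqrt{\nabla\phi^T\mathbf{G}
\nabla\phi})$ lagged one step, which keeps the step-function release
bounded within [−0.05, 1.05].  Time stepping is implicit backward Euler at
the save cadence (0.02 s) — unconditionally stable, so the scalar step may
exceed the flow step.

The release is a 3.5 cm cube of $\phi = 1$ at the junction center with
$\phi = 0$ clamped at the inlets.  $\kappa$ is never stated in the source
study; the default $10^{-4}$ cm²/s is advection-dominated and numerically
benign, and no acceptance quantity depends on its exact value.  The
washout time is per-node $T = t_{1\%} - t_{\max}$, where $t_{\max}$ is the
*earliest* time of the nodal maximum (plateau ties resolve early) and
$t_{1\%}$ the first subsequent crossing of 1% of that maximum, linearly
interpolated between snapshots; nodes that never cross before the 5 s
horizon are censored and reported as such, never extrapolated.  The mean
washout over the release region is volume-weighted (lumped nodal mass)
over uncensored nodes, with the censored fraction alongside.

## Agreement statistics

`synth_mcl_measurements()` fabricates paired bench data as model + bias +
Gaussian noise (seeded), standing in for the mock loop; `bland_altman()`
reports the mean difference, its t-based 95% CI (n = 15 pairs in the source
comparison makes t appropriate; the study does not state its CI method),
and 1.96-SD limits of agreement.  The study's printed CI "[0.24 −0.71]" is
read as the typographically scrambled interval [−0.71, 0.24]; it is never
used as a numeric test input because the underlying pairs are only plotted.
Default synthetic-measurement parameters (bias 0.23 mmHg, noise SD
0.25 mmHg) place the synthetic bias at the magnitude of the study's
reported mean difference.

## Problem sizes and the desk-scale gap

The acceptance profile runs the 3D junction at h = 0.3 cm (≈13 k
tetrahedra) with steady solves, the washout stage at CO = 3 L/min on the
frozen steady field, and the mesh-sensitivity triple as nested uniform
refinements of one h = 0.88 cm discretization (halving each level,
≈0.6 k/4.8 k/38 k cells), each level warm-started by exact prolongation of
the previous solution and solved by modified Newton (factorization reuse,
per-node interleaved sparse ordering) near the root.  Nesting matters:
independently generated surface-snapped meshes change the *geometry* with
h (port areas, staircase remnants), and that geometric drift — not
discretization error — dominates their level-to-level differences.  The planar junction analog
(h ≈ 0.12 cm) backs the sweep-style property tests.  For comparison, the
source study used 7.9 M elements on the real pump CAD.

Two desk-scale consequences deserve explicit note.  First, absolute
pressure losses at ≈13 k cells carry O(10%) discretization error and the
blank housing's bulge recirculation is resolution-sensitive.  Second, the
idealized smooth bicone *streamlines* the head-on collision of the caval
jets — precisely its design intent — while lacking the real pump's blade
and strut drag; at this scale the insert-minus-blank pressure increment
therefore comes out *negative* (the insert model loses less pressure than
the blank housing), which satisfies the clinical bound the study argues
for (< 2 mmHg across the device, increment ≤ 0.7 mmHg) while differing in
sign from the bench increment measured on the true geometry.  Passing
these bounds at desk scale demonstrates that the pipeline reproduces the
study's *conclusions* under its stated operating conditions, not that a
13 k-element idealized mesh reproduces 7.9 M-element proprietary-CAD
numbers.

What the synthetic data do not emulate: pulsatile/respiration-dependent
inflow (steady inflow only, as in the bench protocol), compliant walls,
non-Newtonian rheology, the secondary flow path, patient-specific anatomy,
and measurement artifacts of physical catheters beyond an additive
bias + noise model.

## Known limitations

* Steady mode reports `unsteady_physics` honestly at operating points with
  genuine shedding (high CO, blank housing); endpoint extraction from such
  a quasi-steady state is an approximation to the time mean.  At
  CO = 11 L/min the finest sensitivity level has no stable steady state at
  all (consistent with the unsteadiness the bench study reports at
  CO ≥ 9): its reported pressure loss is the deterministic state after a
  fixed pseudo-step budget from the prolonged coarse solution, and the
  nested-mesh relative difference carries the shedding fluctuation
  (tens of percent) rather than pure discretization error.  The 3%
  mesh-independence the full-scale study reports is not reproducible
  under these desk-scale conditions.
* Dye concentrations are strictly bounded (overshoot within 5%) on
  quality meshes, as the transport oracles assert; on the snapped junction
  meshes the sliver cells left by boundary projection admit local
  excursions up to roughly ±0.35 around the release transient.  The
  washout-time field, which depends on per-node decay times rather than
  extreme values, is insensitive to these excursions.
* The SDF-snapped junction meshes under-resolve port cross-sections by
  O(h) (labeled port area ≈ 15% low at h = 0.3), which slightly raises
  entrance losses; fluxes are exact because inflow is prescribed
  discretely and outflow integrates the labeled faces.
* Gradient recovery at walls is first-order; wall-shear oracles need
  boundary-layer meshes to reach 10% accuracy.
* The 2D junction analog is a verification vehicle, not a physics claim:
  planar vortices persist where 3D ones break down, so it is not used for
  any graded quantity at high CO except where noted.
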