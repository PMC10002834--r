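# fontanflow

Desk-scale evaluation of the **passive ("failed pump", 0 RPM) hemodynamics
of a cavopulmonary assist device** seated in an idealized total
cavopulmonary connection (TCPC).

Fontan patients have no subpulmonary ventricle; a rotary pump suspended in
the cavopulmonary junction can restore the missing 5–7 mmHg pressure rise,
but because such a device sits in series with the entire venous return, the
decisive safety question is what happens when it *stops*: a resting
obstruction of ≥ 2 mmHg across a Fontan pathway is clinically significant.
`fontanflow` is for researchers in computational hemodynamics and
cardiovascular device development who want a self-contained, fully
synthetic replica of that evaluation pipeline — no CAD files, no bench
data, no solver binaries.

The package provides:

* **Synthetic geometry and meshing** — a planar four-port cross junction
  (1.91 cm tubes, 3.4 cm bulged housing, ports 5 cm out), with an optional
  static biconical pump insert (blade heights 1.09 / 1.62 mm as annular
  ridges, four support struts), meshed natively into labeled tetrahedra
  (signed-distance background grid with boundary snapping); structured
  boundary-layer pipe meshes and a cheap planar (2D) junction analog for
  verification.  Gmsh 4.1 and VTU import/export.
* **A stabilized finite-element flow solver** — equal-order P1–P1
  incompressible Navier–Stokes with SUPG/PSPG and grad-div stabilization,

  $$B_G(\mathbf w,q;\mathbf v,p)=\int_\Omega \mathbf w\cdot(\rho\mathbf v_{,t}+\rho\mathbf v\cdot\nabla\mathbf v)\,d\Omega+\int_\Omega\nabla\mathbf w:(-p\mathbf I+\boldsymbol\tau)\,d\Omega-\int_{\Gamma_h}\mathbf w\cdot\mathbf h\,d\Gamma+\int_\Omega q\,\nabla\cdot\mathbf v\,d\Omega=0,$$

  parabolic inlets with exact discrete flux, resistance outlets
  $\mathbf h=-RQ\mathbf n$ (implicit coupling), outlet backflow
  stabilization, generalized-α transients and a pseudo-transient steady
  mode with viscosity continuation.
* **Endpoints** — wall traction
  $\boldsymbol\tau=\boldsymbol\sigma\mathbf n-(\boldsymbol\sigma\mathbf n\cdot\mathbf n)\mathbf n$,
  TAWSS $=|\tfrac1T\int_0^T\boldsymbol\tau\,dt|$, OSI
  $=\tfrac12(1-|\int\boldsymbol\tau\,dt|/\int|\boldsymbol\tau|\,dt)$,
  low-WSS area fraction (TAWSS < 5 dyn/cm²), cut-plane pressures at 4 cm,
  pressure loss, RPA/LPA flow split, and hydraulic power loss in mW.
* **Virtual-dye washout** — stabilized advection–diffusion of a 3.5 cm dye
  cube on the frozen flow, with the per-node washout time
  $T(\mathbf x)=t_{1\%}-t_{\max}$ and volume-weighted regional means.
* **Validation statistics** — synthetic mock-circulatory-loop (MCL)
  measurement generation (bias + noise, seeded) and Bland–Altman agreement
  analysis with t-based confidence intervals and 1.96-SD limits of
  agreement, plus Pearson correlation.

Operating points mirror the bench protocol: cardiac output 3–11 L/min,
60/40 IVC/SVC split, blood-analog fluid (ρ = 1.06 g/cm³, μ = 0.035 P), and
outlet resistances 204.51 / 222.49 dyn·s/cm⁵.  All units are CGS;
pressures are reported in mmHg (1 mmHg = 1333.22 dyn/cm²).

## A worked example

The planar junction analog runs a full case in seconds; the 3D junction
takes a couple of minutes per operating point.

```r
library(fontanflow)

cfg <- run_config(models = "blank", CO_values = c(3, 5, 7),
                  target_h = 0.12, dim = 2L,
                  stats_noise_sd = 0.1, seed = 1)
sw <- sweep_cases(cfg)
print(sw$comparison, digits = 3)
#>   CO_L_min model dP_cfd dP_mcl difference
#> 1        3 blank  0.144  0.312     -0.167
#> 2        5 blank  0.329  0.577     -0.248
#> 3        7 blank  1.256  1.402     -0.146
print(sw$bland_altman)
#> Bland-Altman (n = 3):
#>   mean difference -0.187 mmHg, SD 0.054
#>   95% CI of mean difference [-0.321, -0.053]
#>   95% limits of agreement  [-0.293, -0.081]
```

`dP_cfd` is the simulated maximum inlet-to-outlet pressure loss between
cut planes 4 cm from the junction center (mmHg), rising with cardiac
output; `dP_mcl` is the synthetic bench measurement (configured bias
0.23 mmHg plus noise), and the Bland–Altman block summarizes their
agreement: the mean difference is the simulation-minus-bench bias and the
limits of agreement bracket 95% of paired differences.

A single 3D case with the static pump insert:

```r
cfg3 <- run_config()
res <- run_case(cfg3, CO = 7, model = "vip162")
res$report$dP_max_mmHg        # ~0.57 mmHg, far below the 2 mmHg threshold
res$report$flow_split_rpa_pct # ~51.8 % to the RPA (resistance divider: 52.1)
```

## Scope

The proprietary pump CAD is not public; the insert here is an idealized
bicone that reproduces the flow blockage and shear surfaces, not the exact
blade shapes.  Rotating-pump performance, compliant walls, non-Newtonian
rheology, patient-specific anatomy and explicit thrombosis kinetics are
out of scope.  See the methods vignette
(`vignettes/passive-performance.Rmd`) for the models, numerical choices
and known limitations.
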