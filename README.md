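# aneuscale

Aspect-ratio scaling of intracranial aneurysm models and Bernoulli
energy-loss metrics.

## What this is for

Comparing hemodynamics across patients confounds the aneurysm with its
parent artery. A longitudinal alternative keeps one aneurysm-plus-vessel
geometry and resizes only the sac, producing a ladder of models with
prescribed aspect ratios (AR = perpendicular height h / neck diameter
D<sub>n</sub>) on an identical parent vessel. Energy loss (EL) between
inlet and outlet planes — and its with-aneurysm vs pre-aneurysm difference
per unit sac volume, EL<sub>dif</sub> = (EL<sub>with</sub> −
EL<sub>pre</sub>)/V<sub>A</sub> — can then be tracked along that growth
trajectory.

`aneuscale` is the geometry and metrics toolkit for that workflow, aimed at
computational-hemodynamics users who bring their own flow solver:

* **Mesh layer** — triangle meshes in mm, ASCII/binary STL I/O, neck-plane
  splitting with exact edge interpolation, planar hole capping,
  watertightness and boundary-loop utilities.
* **Morphometry** — h (dome apex distance to the neck plane),
  D<sub>n</sub> = 2√(A/π) (effective circular neck diameter), AR, and sac
  volume V<sub>A</sub> by divergence-theorem integration of the capped sac.
* **Graded sac scaling** — after rigid alignment of the neck plane to XY,
  each vertex above the plane scales about the neck centre by diagonal
  factors 1 + {a,b,1}·(z − z<sub>m</sub>)(k − 1)/h, growing from 1 at the
  neck to k at the dome. The parent vessel and the neck stay bit-identical;
  `solve_scaling_factor()` turns a target AR into the height-exact k.
* **Pre-aneurysm reconstruction** — sac removal plus a deterministic planar
  cap at the neck, leaving inlet/outlet rims untouched.
* **Energy loss** — instantaneous Bernoulli balance
  EL = v<sub>i</sub>A<sub>in</sub>(P<sub>i</sub> + ½ρv<sub>i</sub>² +
  ρgz<sub>i</sub>) − Σ<sub>o</sub> v<sub>o</sub>A<sub>o</sub>(P<sub>o</sub>
  + ½ρv<sub>o</sub>² + ρgz<sub>o</sub>) in W, cycle means over uniform
  pulse grids, EL<sub>dif</sub> in W/m³ and mW/mm³, and Reynolds numbers
  (defaults ρ = 1050 kg/m³, μ = 0.0035 Pa·s).
* **Synthetic fixtures** — a deterministic idealized sidewall aneurysm
  (cylindrical vessel + spherical-cap sac with closed-form morphometry), a
  pulsatile cardiac waveform with exact sampled mean/peak, and analytic
  Poiseuille / prescribed-EL flow series.

No flow field is ever solved here: FSI simulation, volumetric meshing and
wall mechanics are out of scope by design.

## Worked example

```r
library(aneuscale)

fx <- make_sidewall_aneurysm()        # 4 mm vessel, 2 mm neck, AR = 1.0
m  <- morphometry(fx$mesh, fx$plane)
m
#> aneurysm morphometry:
#>   height h        2.0000 mm
#>   neck D_n        1.9953 mm
#>   aspect ratio    1.0023
#>   sac volume      7.2956 mm^3

series <- generate_series(fx$mesh, fx$plane, standard_ar_series())
data.frame(target = standard_ar_series(),
           k = sapply(series, `[[`, "k"),
           measured = sapply(series, function(s) morphometry(s$mesh, fx$plane)$AR))
#>   target      k measured_AR
#> 1    0.3 0.1647      0.3017
#> 2    0.5 0.4988      0.5017
#> 3    0.7 0.6984      0.7014
#> 4    1.0 0.9977      1.0000
#> 5    1.3 1.2970      1.2974
#> 6    1.5 1.4965      1.4950
#> 7    1.7 1.6960      1.6921
#> 8    2.0 1.9953      1.9868
```

The measured D<sub>n</sub> is 0.23% under the analytic 2 mm (inscribed
polygon + chord sagitta at the default 0.25 mm resolution), so the
measured AR of the input is 1.0023; every re-measured AR lands within 1%
of its target. Note the k = 0.165 entry: below a height ratio of 1/2 the
graded transform's axial map is non-monotone, and
`solve_scaling_factor()` switches to the height-exact branch
k = 1 − 1/(4r) (see the methods vignette).

```r
pre <- make_pre_aneurysm(fx$mesh, fx$plane)   # capped vessel, rims untouched
fluid <- fluid_properties()                    # rho 1050, mu 0.0035, g 9.81
pair <- make_paired_el_series(2e-3, 1e-3, n_steps = 800)
res <- el_result(pair$with, pair$pre, V_A = m$V_A * 1e-9, fluid)
#> EL_with = 0.002 W, EL_pre = 0.001 W, EL_dif = 0.1371 mW/mm^3

wf <- make_pulsatile_waveform()                # mean 0.25, peak 0.6 m/s, n = 800
reynolds_mean(fluid, wf$v, 0.004)
#> [1] 300
```

The paired series are constructed to have cycle-mean losses of exactly 2
and 1 mW, so EL<sub>dif</sub> = 1 mW / 7.2956 mm³ = 0.137 mW/mm³; the
default waveform keeps a 4 mm vessel at cycle-averaged Re = 300, inside
the laminar regime (Re < 760) assumed for these models.

A command-line wrapper with subcommands `synth`, `morph`, `scale`,
`preaneurysm` and `el` is installed at
`system.file("cli", "aneuscale", package = "aneuscale")`; every run writes
a JSON manifest of its resolved parameters, and a YAML config can supply
defaults (see `?aneuscale_run`).

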