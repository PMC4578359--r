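---
title: "Graded aspect-ratio scaling of aneurysm models and Bernoulli energy-loss metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graded aspect-ratio scaling of aneurysm models and Bernoulli energy-loss metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuscale)
```

## Background and scope

Rupture-risk studies of intracranial aneurysms usually compare cohorts of
patients observed once ("horizontal" analysis). A longitudinal alternative is
to take a single aneurysm-plus-parent-vessel geometry and resize only the
sac, producing a family of models that differ in aspect ratio
(AR = perpendicular height / neck diameter) while the parent artery — the
main confounder across patients — stays exactly fixed. Hemodynamic
quantities, in particular the energy loss (EL) between inlet and outlet test
planes, can then be tracked along that synthetic growth trajectory.

`aneuscale` implements the geometric and bookkeeping half of that program:

* a triangle-mesh data model with STL input/output,
* neck-plane splitting, hole capping and morphometry (h, D~n~, AR, V~A~),
* the height-graded sac-scaling transform and the solved scaling factor k,
* pre-aneurysm vessel reconstruction (sac removal + planar cap),
* the Bernoulli energy-loss metrics (instantaneous EL, cycle mean,
  volume-normalized EL difference) and Reynolds characterization,
* deterministic synthetic fixtures (idealized sidewall aneurysm, pulsatile
  waveform, analytic Poiseuille series).

It deliberately does **not** solve any flow field: no Navier–Stokes/FSI
solver, no volumetric meshing, no wall mechanics, no streamline
classification. The energy-loss functions post-process plane-averaged flow
data (from a CFD solver, an experiment, or the package's analytic
generators).

## The graded scaling transform

After a rigid alignment that makes the neck plane the plane z = z~m~
(`neck_alignment_transform()` composes rotations about X and Y; no Z
rotation is needed to align a normal), every vertex strictly above the
plane is mapped by a diagonal, height-dependent scaling about the neck
centre (x~m~, y~m~, z~m~):

$$
x_t = x_m + \left(1 + \frac{a\,\zeta\,(k-1)}{h}\right)(x - x_m),\qquad
y_t = y_m + \left(1 + \frac{b\,\zeta\,(k-1)}{h}\right)(y - y_m),\qquad
z_t = z_m + \left(1 + \frac{\zeta\,(k-1)}{h}\right)\zeta,
$$

with $\zeta = z - z_m$, h the perpendicular height, k the scaling factor and
a, b transverse coefficients (default 1; the axial direction carries no
coefficient). The per-vertex factor grows linearly from 1 at the neck to k
at the dome, so:

* vertices at or below the plane are bit-identical to the input (the parent
  artery and the neck are *kept*, not merely approximated);
* the surface is continuous across the neck (the factor tends to 1);
* for k > 1 the expansion rate increases monotonically from neck to fundus,
  the intended growth pattern.

### Solving k from a target AR

Because the neck is fixed, retargeting AR is retargeting the height. The
axial map $\zeta \mapsto \zeta\,(1 + \zeta (k-1)/h)$ is quadratic in
$\zeta$. For $k \ge 1/2$ it is monotone on $[0, h]$, the apex image
$k\,h$ is the new height, and the exact factor for a height ratio
$r = \mathrm{AR}_{target}/\mathrm{AR}_{current}$ is simply $k = r$.

For $k < 1/2$ the map folds over: its maximum on $[0,h]$ is interior, at
$\zeta^\* = h / (2(1-k))$, with value $h/(4(1-k))$. Points *below* the apex
then end up higher than the apex image, and a naive $k = r$ would deliver a
model whose re-measured height is $h/(4(1-k))$, not $r\,h$ (for r = 0.3
that is a 19% error). `solve_scaling_factor()` therefore uses the
height-exact piecewise law

$$
k =
\begin{cases}
r, & r \ge 1/2,\\[2pt]
1 - \dfrac{1}{4r}, & 1/4 < r < 1/2,
\end{cases}
$$

which is continuous at r = 1/2 and makes the re-measured height equal
$r\,h$ exactly in both regimes. Ratios $r \le 1/4$ are unattainable with
positive scaling factors and are rejected with an error. A corollary worth
knowing: below r = 1/2 the scaled dome is no longer geometrically similar
to a shrunken original — its highest point is a ring of former mid-height
material, which is the transform's literal behaviour, not an artifact of
this package.

The "height law" (measured height scales by k; hence AR~out~ = k·AR~in~)
holds exactly for $k \ge 1/2$ and is tested in that regime.

### Numerical choices

* On-plane classification uses a 1e-9 mm tolerance; on-plane vertices
  belong to the vessel side and are tagged `neck`, because the transform
  applies strictly above the plane.
* Transverse and axial factors are checked to be positive before any
  vertex moves; a non-positive factor (possible with large a, b and small
  k) aborts with "transform inverts geometry".
* `generate_series()` continues past per-target failures, recording the
  error message in that series slot.
* Scaled meshes are returned in the input frame by default (the rigid
  alignment is inverted after scaling); `aligned = TRUE` skips the
  inverse map.

## Morphometry conventions

* **Height** is the maximum signed vertex distance to the neck plane (the
  dome apex), not a centroid distance.
* **Neck diameter** is the effective circular diameter
  $D_n = 2\sqrt{A/\pi}$ of the neck polygon. This is exact for circular
  necks and well-defined for irregular outlines; a maximum-chord convention
  would be noisier and is not used.
* **Sac volume** caps the sac at its neck boundary loop (fan triangulation
  about the loop centroid) and integrates the divergence-theorem sum of
  signed tetrahedra; orientation is repaired by global sign before taking
  the magnitude.
* The neck centroid used as the scaling centre is the area-weighted polygon
  centroid of the neck curve.

AR and V~A~ are invariant under rigid motions to ~1e-12 relative (tested at
1e-9), and V~A~ scales as s³ under uniform scaling.

## Energy-loss metrics

The instantaneous loss between the inlet plane and the outlet planes is the
Bernoulli energy-flux balance

$$
EL = v_i A_{in}\left(P_i + \tfrac12 \rho v_i^2 + \rho g z_i\right)
   - \sum_{o} v_o A_{o}\left(P_o + \tfrac12 \rho v_o^2 + \rho g z_o\right)
  \quad [\mathrm{W}],
$$

with P the **static** pressure, so that $P + \tfrac12\rho v^2$ is the total
pressure. (Reading P itself as total pressure would double-count the kinetic
term; both readings are computable from the same inputs, static is the
implemented default.) The balance is printed for a single outlet in the
source literature; summing the outlet term over several planes is the
natural energy bookkeeping for bifurcating vessels and reduces to the
printed form with one outlet.

* Cycle averaging is a plain arithmetic mean over a uniform grid (default
  n = 800 steps per pulse); non-uniform grids are rejected rather than
  silently reweighted.
* Plane elevations default to 0, so gravity terms cancel unless elevations
  are supplied; with g = 0 and equal elevations results are bit-unchanged.
* `el_dif()` reports (EL~with~ − EL~pre~)/V~A~ in W/m³ and mW/mm³
  (1 W/m³ = 1e-6 mW/mm³). It is antisymmetric in its two conditions.
* Mesh coordinates are millimetres (clinical 3DRA convention); all flow
  quantities are SI. The only unit conversions live at the energy-loss /
  CLI boundary (mm³ → m³, mm → m).
* Fluid defaults: ρ = 1050 kg/m³, μ = 0.0035 Pa·s (the viscosity is quoted
  in the source as "0.0035 Pa", an obvious unit slip for Pa·s), g = 9.81
  m/s².

The implementation is validated against a Hagen–Poiseuille closed form
($EL = Q\,\Delta P$ with $\Delta P = 8\mu L Q/(\pi R^4)$) across a seeded
sweep of radii, lengths and velocities, against a brute-force re-summation
of the cycle mean, and against pressure-gauge invariance on
mass-conserving series.

## The synthetic fixtures

No patient 3DRA geometry is public, so all tests run on generated inputs.

**Sidewall aneurysm.** A straight open-ended cylinder (axis x, radius
2 mm, length 24 mm by default) carries a spherical-cap sac seated
tangentially on the vessel top line. The neck plane is the tangent plane
z = R~v~; the sac's neck circle (diameter 2 mm by default) lies in it, and
h = AR·D~n~ fixes the cap sphere (radius $(a^2+h^2)/(2h)$). Every
morphometric quantity has a closed form, including
$V_A = \pi h^2 (3r - h)/3$. Construction details that matter:

* The sac shell continues a short skirt below the plane and is closed by a
  flat disk, so the plane cuts it transversally in exactly one loop; the
  cylinder's azimuthal grid is pinned so the tangent line is an exact
  vertex row (on-plane vertices, assigned to the vessel side).
* The vessel and sac shells are built as separate surface components with
  exact analytic coordinates rather than a boolean union; all package
  operations are topology-based and indifferent to this, and it keeps the
  generator fully deterministic and closed-form-checkable.
* The sac is sampled at half the nominal edge length (curvature-adaptive
  sampling: the sphere is the high-curvature region), which is what puts
  re-measured AR within 1% at the default 0.25 mm resolution.
* The `seed` rotates the sac's azimuthal sampling phase; outputs are
  bit-identical for a fixed seed and parameters.

What the fixture does *not* emulate: vessel curvature, tapering, the
ICA–PComA bifurcation, irregular neck outlines, or surface noise from
image segmentation. Tests passing on the fixture therefore demonstrate the
correctness of the transforms and metrics, not robustness to messy
clinical meshes (duplicate-vertex merging is the only repair implemented;
heavily non-manifold input is rejected, not fixed).

**Pulsatile waveform.** A smooth periodic template (two von-Mises-type
lobes: systolic peak at 20% of the cycle, dicrotic bump at 55%) is sampled
on the uniform grid, then shifted and rescaled so the sampled mean and
maximum equal the requested values exactly. Defaults (period 0.8 s, mean
0.25 m/s, peak 0.6 m/s, n = 800) keep a 4 mm vessel at a cycle-averaged
Re ≈ 300, well inside the laminar bound Re < 760 assumed for this class of
simulation. The template shape is fixed; only period, mean, peak and step
count are parameters, and requests that would drive the waveform negative
are rejected.

**Poiseuille and paired-EL series.** `make_poiseuille_series()` builds
steady inlet/outlet samples whose exact loss $Q\,\Delta P$ is attached for
assertion; `make_paired_el_series()` builds two pulsatile-pressure series
whose cycle-mean losses equal prescribed targets, for round-trip tests of
`el_dif()`.

## Pre-aneurysm reconstruction

`make_pre_aneurysm()` removes the sac and closes the neck with a flat
planar fan cap — deterministic and exactly testable (the added area equals
the neck polygon area), unlike a manual CAD patch. Laplacian smoothing of
the cap region is available but off by default, and inlet/outlet rims are
never moved, so boundary conditions remain comparable between the
with-aneurysm and pre-aneurysm runs. Reconstructing a hypothetical healthy
curvature through the neck is out of scope. At default fixture parameters
the entire reconstruction lies within one nominal edge length
(max offset $\sqrt{a^2+R_v^2} - R_v \approx 0.24$ mm) of the analytic
cylinder.

## Problem sizes and determinism

The default fixture has ≈ 6,000 vertices / 12,000 faces; a full
eight-model series with per-model re-measurement runs in about one second,
and the whole test suite (including 100-mesh transform-oracle sweeps and
seeded Poiseuille sweeps) in well under a minute. All randomness — fixture
phase, property-test draws, pulsatile phases — is seeded, and every
generator is bit-deterministic given its arguments.

## Known limitations

* Mesh repair is limited to duplicate-vertex merging; self-intersection
  testing of cap loops is limited to repeated-vertex detection.
* Element quality degrades near the dome at large k (topology is
  preserved, no remeshing is performed) — acceptable for morphometry,
  but a CFD user should remesh before solving.
* Multi-loop neck intersections are an error by design (one physician
  plane, one neck), not resolved heuristically.
* The transverse coefficients a, b default to 1 (isotropic dome scaling);
  values fitted to observed growth patterns are study-specific inputs, not
  package defaults.
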