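---
title: "Cell-resolved wall shear stress in microvessels: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-resolved wall shear stress in microvessels: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(microwss)
```

## What the package computes

`microwss` simulates blood flow in microvessel geometries with every red
blood cell (RBC) resolved as a deformable membrane, and quantifies the wall
shear stress (WSS) and its surface gradient (WSSG) that the flow exerts on
the vessel wall. Endothelial cells respond to both the magnitude and the
spatial gradient of WSS, and in vessels of 6–24 µm the particulate nature of
blood makes both quantities strongly heterogeneous; resolving single cells
is the only way to capture that heterogeneity. The package provides the
whole chain at desk scale: synthetic vessel geometry, membrane mechanics,
a fluid–structure solver, and the WSS/WSSG statistics layer.

## Geometry generation

Vessel geometries are unions of circular-section vessels swept along
polyline centerlines. Tubes (`make_tube()`) are structured swept meshes with
parallel-transported frames, so every vertex carries exact arc-length and
angular coordinates; junctions and networks (`make_junction()`,
`build_network()`, `make_junction_loop()`) are meshed by marching
tetrahedra on the capsule-union signed distance field, which also backs grid
classification and wall projection everywhere else. Morphometry follows the
microvascular ranges: diameters 6–24 µm, vessel lengths 25–165 µm, three
Strahler orders with Horton's diameter ratio (default 1.6) linking
consecutive orders, and sinusoidal centerline tortuosity with amplitude
`tortuosity × diameter`. A junction region of interest extends one feeder
diameter from the junction center (configurable); the junction fillet
geometry is whatever the capsule union produces — sharper than a CAD blend,
which concentrates the local WSS maxima slightly.

Flow fixtures are periodic in the axial (z) direction: tubes close onto
themselves, and the junction fixture is a feeder that splits into two
branches which merge back into the feeder within one period, with both ends
of the periodic box placed in plain feeder cross-sections so the wrap is
geometrically exact. Driving is a mean axial pressure gradient restricted to
the lumen (`pressure_drop`, the 0.3–1.0 Pa/µm physiological range) or a
feedback-controlled gradient that holds a target volumetric flow rate
(`inlet_flow_rate`). This replaces inlet/outlet cap boundary conditions,
which belong to cluster-scale network runs; it keeps the pressure solve
exact and lets cells recirculate naturally, which is also how the feed
hematocrit is maintained: a cell whose centroid crosses the outlet plane
re-enters at the inlet with its current shape.

## Membrane mechanics

The resting RBC is the biconcave discocyte with end-to-end diameter 7.8 µm;
the Evans–Fung thickness profile (coefficients 0.207, 2.003, −1.123)
reproduces the canonical surface area 134.1 µm² and volume 94.1 µm³ within
1% on a subdivided-icosahedron triangulation (level 5; level 3 is used in
flow, level 4 for geometry checks).

In-plane elasticity follows the Skalak law,
`W = Gs/4 (I1² + 2 I1 − 2 I2) + Gs·C/4 · I2²`, with shear modulus
`Gs = 2.5×10⁻⁶ N/m` and dilation ratio `C = 100` (near-incompressible
membrane); bending follows the Helfrich energy
`E = kb/2 ∮ (2H − c0)² dA` with `kb = 2.7×10⁻¹⁹ J` and `c0 = 0`. These
moduli are standard literature values for human RBCs; they are parameters of
`make_biconcave()`.

Two discretization choices matter:

* The Skalak element is formulated purely in squared edge lengths of each
  triangle (deformed Gram matrix against the reference Gram matrix), so the
  energy is exactly invariant under rigid motions and its analytic gradient
  is short. Forces vanish identically at the reference shape.
* The bending energy uses the cotangent Laplacian for the mean-curvature
  magnitude with barycentric (one-third) vertex areas, and the force is the
  exact analytic gradient of that discrete energy — differentiating the cot
  weights, the edge differences, and the areas. Barycentric rather than
  mixed Voronoi areas keep the gradient exact and cheap. A finite-difference
  oracle reproduces every force component to 10⁻⁵ relative for both
  operators. Known limitation: at the 12 valence-5 vertices of the
  icosahedral triangulation the pointwise bending force on a perfect sphere
  does not converge to zero under refinement (the mean does, reaching 0.2%
  of a flattened-sphere force scale at level 5); this is a standard property
  of the cotangent operator at exceptional vertices and is immaterial once
  the membrane deforms.

## Flow solver

The fluid obeys the unsteady Stokes and continuity equations (convective
inertia is negligible at these scales) on a uniform staggered Cartesian
grid, default spacing `h = 0.5 µm`, with plasma viscosity 0.001 Pa·s outside
cells and 0.005 Pa·s (hemoglobin) inside, blended over a ≈2-cell transition
band by an indicator function obtained by spreading the membrane surface
normals and solving one Poisson equation.

Time stepping is an incremental pressure-correction projection:

1. **Viscous update, delta-form ADI.** The increment solves
   `(I − a Dxx)(I − a Dyy)(I − a Dzz) δu = Δt/ρ · RHS(uⁿ)` with
   `a = Δt·µmax/ρ`, one batched tridiagonal solve per direction. Solid and
   ghost rows are identity rows, so implicit diffusion never couples across
   the wall, and because the scheme is in delta form its steady state
   satisfies the unsplit discrete balance `0 = −∇p + ∇·τ + f` exactly with
   the ghost-node wall values. The variable-viscosity stress divergence
   (harmonic face averaging) and the IBM force enter the explicit RHS.
2. **Walls.** No-slip on the curved wall is enforced by sharp-interface
   ghost nodes: each solid node adjacent to fluid receives the quadratic
   reflection through `u(wall) = 0` and two interior samples along the
   local normal, with the ghost–ghost stencil coupling solved exactly by a
   cached sparse factorization. Fluid nodes grazing the wall (within 0.2 h)
   are treated as wall — the standard cut-cell small-cell remedy, without
   which such nodes host a near-neutral creeping mode. The observed
   convergence order of the Poiseuille solution, measured at fixed physical
   probe points, is 1.8–2.1.
3. **Projection.** An FFT Poisson solve on the periodic box; the discrete
   divergence of every cell is zero to rounding after each step.
4. **Cells.** Membrane forces are spread with the Peskin 4-point kernel and
   vertices move with the kernel-interpolated velocity (adjoint pair, so
   the total force is conserved exactly). All cells are pooled into one
   block membrane per step.

The time step is accuracy-limited rather than stability-limited: the
implicit fluid solve is unconditional and the membrane coupling is
overdamped, so pushing Δt up degrades membrane area conservation long
before anything blows up. `stable_dt()` returns the smaller of the
drag-balance relaxation times of the stiffest elastic mode
(`3πµh/(Gs(1+C))`) and of bending (`3πµh³/kb`), each with a safety factor
0.5, and an accuracy cap of `5×10⁻⁶ s × h/0.5 µm` with cells (2×10⁻⁶ s for
plasma transients). When a membrane
is strongly strained (junction apices, tight squeezes — the Skalak law
stiffens with strain) the driver subdivides the step by up to 8 internally.
Production cell runs use Δt = 2.5×10⁻⁶ s at `h = 0.5 µm` (the accuracy cap
was calibrated by a Δt-refinement study of membrane area conservation at
capillary speeds of ≈0.6–0.9 mm/s). Plasma steady states are obtained by a
short physical transient at Δt = 2×10⁻⁶ s followed by a few hundred
settling steps at Δt = 10⁻⁴ s: the delta-form splitting converges to its
(Δt-independent) steady state at an asymptotic rate of about 0.9997 per
step, so the per-step change after this schedule sits at ~10⁻⁶ of the
velocity scale and keeps decaying.

## WSS and WSSG extraction

The traction at each wall-mesh vertex is expressed in a local cylindrical
frame: `e_r` the inward normal, `e_s` the direction of the near-wall flow
(from the velocity at a probe one stencil-span inside the wall; stagnant
vertices fall back to the vessel centerline tangent and are flagged), and
`e_θ = e_r × e_s`. The components are `t_s = µ ∂u_s/∂r`,
`t_r = −p + 2µ ∂u_r/∂r`, `t_θ = µ ∂u_θ/∂r`; in a steady plasma tube the
latter two are many orders of magnitude below `t_s`, and `t_s` is the WSS
τ, reported in dyne/cm² (1 Pa = 10 dyne/cm²).

The radial derivative uses the one-sided second-order stencil
`f'(0) = (4 f(d) − f(2d))/(2d)` with a total span of 0.3 µm — inside the
cell-free layer, which is why the plasma viscosity is always used. Because
0.3 µm is below the grid spacing, the stencil-point velocities come from a
no-slip-constrained quadratic radial fit `u(r) = c1 r + c2 r²` to samples at
depths `(1, 1.5, 2) h` along the inward normal, each sample interpolated
with a bias-corrected (tri-quadratic) scheme that removes the second-order
error of trilinear interpolation. The span shrinks once (and the vertex is
flagged invalid if still unresolvable) where the lumen is too thin.

WSSG is the central difference of τ along `e_s` and `e_θ`: the stencil
endpoints step half a span along the tangent, are projected back to the
surface through the signed distance field, and τ there is interpolated by a
local linear (moving-least-squares) fit over the nearest valid vertices —
exact on linear fields, which fixes the order of the stencil. On the
discrete cylinder the extracted τ carries a staircase-induced angular
ripple of a few percent; the resulting WSSG noise floor is about
0.2–0.5 τ/D at `h = D/20` in the mean absolute components (the signed ROI
means vanish by symmetry). An optional MLS smoothing pass on τ
(`smooth_iters`), itself exact on linear fields, reduces the floor about
fourfold and is used for fixture-level gradient statistics.

ROI statistics follow the standard definitions: area-weighted ROI average
`τ̄ = ΣτdA/A` with barycentric vertex areas as `dA`; per-vessel normalized
standard deviation `τ' = (1/τ̄)·sqrt(Σ(τi − τ̄)²/(N − 1))`; temporal
absolute RMS (vertex RMS about the vertex time mean, averaged over the ROI)
and relative RMS (vertex RMS scaled by the magnitude of the ROI
time-averaged value — the absolute value resolves the sign ambiguity for
signed WSSG means). The two uses of "τ'" in the field (spatial standard
deviation versus temporal RMS) are kept apart as `vessel_std()` and
`temporal_rms()`. Sampling for time averages runs at the 0.5 ms cadence.
RBC-influence ratios `τ̄_RBC/τ̄_pl` are ratios of ROI averages and require
both runs to have used the flow-rate boundary condition, because only then
do wall-stress changes express the cellular influence rather than the
boundary forcing.

At bifurcations, the flow ratio `Q1* = Q_D1/Q_F` integrates the
time-averaged normal velocity over gate discs placed mid-vessel, and the
cell-flux ratio `N1* = N_D1/N_F` counts centroid crossings of the same
gates; branch 1 is by convention the higher-`Q*` branch, so the
phase-separation measure `N1* − Q1*` is positive when cells
disproportionately follow the stronger branch (plasma skimming).
`phase_separation_vs_wss()` regresses this measure against the daughter WSS
discrepancy by ordinary least squares.

## What the synthetic conditions do and do not emulate

The desk-scale fixtures reproduce the governing physics — deformable cells
in unsteady Stokes flow, sharp walls, physiological driving pressures
(0.3–1.0 Pa/µm), feed hematocrits up to 30%, the 0.5 ms averaging cadence —
on single tubes, curved tubes, and one bifurcation/convergence loop with
horizons of 6–20 ms and grids below 5×10⁴ cells. They do not reproduce
cluster-scale network runs (≈8×10⁷ grid points, 138 vessels, 0.7 s of
physical time), so network-level magnitudes (e.g. the ≈3× venular WSS
amplification, the 3–3.5 dyne/cm²/µm junction WSSG means, or the 83%
circumferential-dominance fraction) are out of reach; the package instead
verifies the mechanisms behind them: profile blunting with cells at matched
flow, `τ̄_RBC/τ̄_pl > 1`, higher WSS on the higher-curvature side of a bent
vessel, the existence of a cell-free layer, increased spatial WSS variation
with cells, and positive phase separation at an asymmetric bifurcation.
Tube fixtures with one cell correspond to tube hematocrits of ≈6–12%, and
resting cells can only be seeded where they fit undeformed. One limitation
is explicit: coupled cell runs through a junction diverge at desk
resolution once a cell engages the bifurcation cone — the extensional
squeeze drives membrane strains whose nonlinear Skalak stiffening outruns
the explicit immersed-boundary coupling at affordable membrane resolutions
(straight-tube cell runs are stable for 20 ms and beyond). Junction flux
partitioning therefore combines the plasma loop run (for `Q*`) with a
finite-size tracer estimator (`tracer_fluxes()`): cell-sized excluded
volumes concentrate admissible centroids toward the axis, and advecting
them through the frozen steady flow reproduces the plasma-skimming sign of
`N1* − Q1*` at negligible cost. RBC aggregation, the glycocalyx,
endothelial nucleus topology and compliant walls are excluded by design.

## Worked example

```{r example}
library(microwss)

tube <- make_tube(diameter = 10, length = 8, mesh_size = 0.5)
attr(tube, "period") <- 8
sys <- flow_system(tube, h = 0.5,
                   bc = list(kind = "pressure_drop", value = 0.1))
state <- flow_state(sys)
for (i in 1:250) state <- step_flow(state, sys, 2e-6)

frames <- local_frames(tube, state, sys)
wss <- wall_shear_stress(state, tube, frames, sys)
roi_average(wss, tube, "vessel:1")   # ~2.5 dyne/cm2 = G R / 2
autoplot(wss)
```

## Reproducing the headline numbers

`scripts/acceptance.R` regenerates every reported quantity from scratch —
geometry, seeding, simulation, extraction — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Problem sizes there match this vignette: the Poiseuille and curved-tube
fixtures, a 20 ms matched-flow-rate pair with one cell in a 10 µm tube, and
the bifurcation loop with its steady plasma flow and 30 finite-size
tracers.
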