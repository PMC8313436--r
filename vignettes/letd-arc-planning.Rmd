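---
title: "Dose-averaged LET optimization for proton arc therapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-averaged LET optimization for proton arc therapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sparclet)
```

## Why optimize LET_d

Clinical proton therapy prescribes physical dose scaled by a constant RBE of
1.1, but the biological effect of protons rises with their linear energy
transfer, which peaks near the end of range. A planning system that can
*place* the high-LET region — concentrating it inside the tumor and steering
it away from adjacent critical organs — adds a biological degree of freedom
at no dose cost. Fixed-beam IMPT has few directions from which to compose
dose, so its leverage over the spatial LET_d distribution is limited;
an arc that delivers spots from a quasi-continuum of gantry angles has far
more. This package implements the joint dose + LET_d inverse-planning
problem for both delivery modes on synthetic phantoms, so the algorithmic
behavior can be studied end to end on one CPU.

## The physics engine

The pencil-beam engine is analytical throughout; it replaces Monte Carlo
transport while preserving the structure the optimizer sees (sparse
per-spot dose and LET columns).

* **Range-energy**: `R = α E^p` cm of water with α = 0.0022, p = 1.77.
  This puts 160 MeV at 17.5 cm, and its derivative reproduces tabulated
  stopping powers (5.2 MeV cm²/g ≈ 0.52 keV/μm at 160 MeV) — one
  self-consistent power law supplies range, depth dose and LET.
* **Depth dose**: the electronic stopping power `S(z) ∝ (R − z)^{1/p − 1}`
  is integrated exactly over each depth cell (the singularity at `z = R` is
  integrable) and convolved with a Gaussian range-smearing kernel whose
  width combines an 80–20 distal falloff floor (3 mm default) with
  straggling `0.012 R^0.935` cm. Curves are tabulated per energy at 0.5 mm
  and linearly interpolated.
* **Depth LET_d**: the dose-weighted mean of the residual-energy stopping
  power under the same kernel, `conv(S·L)/conv(S)`. `L` is capped at the
  stopping power of a 2 MeV proton (≈15 keV/μm); an uncapped `L` diverges
  at zero residual energy, and scored Monte Carlo LET_d is likewise bounded
  by its scoring resolution. The cap is a *calibration* of the engine:
  entrance values match stopping-power tables, the distal falloff exceeds
  the peak which exceeds the entrance, and an energy-stacked SOBP (16 cm
  range, 6 cm modulation) yields a mid-plateau LET_d between 2 and
  3 keV/μm, the textbook band. `build_sobp()` recomputes this.
* **Lateral model**: one Gaussian per spot; σ(depth) adds a 4 mm in-air
  sigma and a multiple-Coulomb-scattering growth of 0.035 mm per mm depth
  in quadrature. There is no nuclear halo: absolute tail dose is
  underestimated, which affects dose conformity mildly and the optimization
  mechanics not at all.
* **Secondary particles** are not transported; their LET contribution is
  folded into the effective depth-LET curve. This is a fidelity limit worth
  remembering when comparing magnitudes with Monte Carlo studies.
* **WEPL** is an exact Amanatides–Woo voxel traversal of the relative
  stopping-power grid, per gantry angle, in compiled code.

Dose is calibrated so a unit-weight (1 MU) spot deposits 5 mGy at its Bragg
peak; with 2–3 Gy fractions this puts typical optimized spot weights in the
0.1–10 MU range, so the 0.02 MU deliverability threshold engages the way it
does clinically.

## Influence matrices and the LET_d quotient

`compute_influence()` assembles matched sparse matrices `D` (Gy/MU) and `L`
(keV/μm) over a scoring mask (the union of the ROIs by default). Entries
below 10⁻⁴ of a spot's column maximum are dropped; the truncation error is
bounded and measured in the tests. Per-voxel dose is the weighted column
sum; dose-averaged LET is the quotient of the weighted sums, with `LET_i = 0`
where dose is zero (the 0/0 case the formulation leaves open). The quotient
obeys three structural invariants the test suite asserts on every plan:
invariance under uniform weight scaling, confinement to the convex hull of
contributing per-spot LET values, and collapse to `LET_ij` for a single
contributor.

## Objective, gradient, solver

The objective is the standard piecewise-quadratic sum: a two-sided term
pulls target dose to the prescription; one-sided (Heaviside-gated) terms
penalize OAR overdose, target LET_d undershoot and OAR LET_d overshoot;
dose-volume terms use the per-evaluation voxel-selection reformulation
(excess voxels closest above the level are pulled to it). LET_d terms are
evaluated only on voxels with positive dose, where the quotient is defined.

The gradient is exact: dose terms contribute `2p Dᵀr`; LET terms use the
full quotient rule `∂LET_i/∂ω_j = (M_ij − LET_i D_ij)/D_i` with
`M = D∘L`, so central finite differences agree to 10⁻⁶ (asserted at 20
random points). Heaviside gates and dose-volume selections are held fixed
at the evaluation point; the one-sided quadratics are C¹, so this is the
true derivative almost everywhere. The LET quotient makes the problem
nonconvex; local minima are accepted, and the deterministic initialization
(uniform weights scaled to the mean-dose prescription) makes every run
reproducible. The solver is bound-constrained L-BFGS-B with ω ≥ 0, at most
200 iterations per round.

Because the dose and LET goals compete, the relative penalty weighting is
a schedule, not a constant: `tune_let_weights()` holds dose penalties fixed
and scales the LET penalties up a geometric ladder (8⁰, 8¹, 8²), then
refines the feasibility boundary by three log-scale bisections, accepting
the largest multiplier whose re-optimized plan keeps target D95 at or above
99% of the dose-only D95. The bisection matters for comparisons: with a
shared coarse ladder, two beam geometries can both stall at the same rung
even though one could tolerate a substantially stronger LET push, which
distorts "achievable LET_d at matched coverage". The default LET goals are
deliberately unattainable (12 keV/μm target floor, 1.5 keV/μm OAR ceiling)
so the terms keep pulling throughout the ramp.

## Arc sequencing

SPArc plans start from 20° control-point sampling (cell centers across the
span, wrapping through 0° for spans like 160°→40°) and halve the spacing
down a 20°→10°→5°→2.5° schedule. At each refinement a control point splits
into children at ±¼ spacing; its energy layers, sorted by summed weight,
are dealt alternately to the children (disjoint and exhaustive; a child
that would be empty receives a zero-weight copy of the strongest layer),
lateral spots are re-placed for the child angles, and the parent layer's
MU is carried over as a warm start — total MU is conserved exactly by the
redistribution, and re-optimization follows. Intermediate rounds use a
60-iteration cap: their solutions are only warm starts for the next
refinement, and the final round and the deliverable re-optimization run at
the full cap. After the final refinement each control point keeps its
single heaviest layer (ties to the lower energy), weights are re-optimized,
and spots below 0.02 MU are removed with the survivors re-optimized under
the active bound. The interleaving order — refine, partition, re-optimize,
then reduce — is one consistent reading of the workflow; the alternative
(reduce before re-optimizing) differs only transiently.

IMPT plans are the same path with one control point per beam, full layer
sets, and no reduction; the LET-free variant zeroes the LET penalties so
both variants share an identical spot set.

## Delivery time

Per control point: spots × 2 ms + (layers − 1) × 0.6 s + MU × beam-on rate
(default 0 s/MU — no dose-rate parameter is modeled). IMPT sums beams plus
optional setup time. SPArc models continuous rotation at 1 rpm as, per
inter-control-point interval, max(travel time, delivery time of the
arriving control point), plus the final coast to the arc stop — so a light
full arc takes exactly 60 s and no arc can beat span/speed. Whether a real
system dwells (stop-and-go) or modulates speed is machine-specific; the
max-composition covers both limits without claiming either.

## Synthetic scenarios and what they do (not) show

Three deterministic phantoms emulate the study geometries: a central
spherical target with posterior/anterior OARs in an elliptical body (full
arc, 78 Gy/39 fx), a lateralized liver-like target with a nested GTV and a
surrounding normal-liver sphere (partial arc 160°–40°, 75 Gy/25 fx), and a
brain-like target flanked by four small OARs (full arc, 54 Gy/30 fx). Each
carries a thin conformity ring (4–10 mm shell) standing in for unclassified
normal tissue. The packaged experiments run at 5 mm isotropic voxels —
chosen so a full SPArc plan optimizes in minutes on one CPU; 2 mm is the
documented default for production-style runs and changes the problem size,
not the code path. Real patient anatomy (heterogeneous densities, irregular
shapes, immobilization devices) is out of scope, so passing comparisons
demonstrate the *mechanism* — more beam directions buy more LET_d
steering — not patient-specific magnitudes. Accordingly the comparison
experiments assert orderings (LET_d non-decreasing with beam count, SPArc
maximal; boost LET_d growing as the boost volume shrinks; arc above
fixed-beam plans in the liver and brain scenarios with every OAR spared),
never the published patient numbers. The LET-volume histograms report only
voxels above 1% of the fraction dose, so the zero-dose LET_d convention
cannot distort them.

## Numerical choices and degenerate inputs

Depth curves: 0.5 mm tabulation, linear interpolation, zero beyond the
table. Influence cutoff 10⁻⁴ per column; spots that miss the scoring volume
keep an all-zero column with a warning. Erosion (`shrink_roi`) acts on the
metric ball in mm (exact on anisotropic grids; an FFT convolution handles
large radii, thresholded at ½, and equals the direct shift construction
exactly); eroding to emptiness warns and legally terminates a shrinking
series. Arc spans smaller than the coarse spacing collapse to one control
point with a warning. An empty control point delivers in 0 s with a
warning; a plan with nonzero weights under 0.02 MU is rejected as
non-deliverable. Ties in layer reduction go to the lower energy; the
child-splitting deal gives the strongest layer to the earlier child. All
pipelines are randomness-free: identical configurations produce
byte-identical plan JSON.

## Known limitations

No nuclear halo or secondary-particle transport; single-Gaussian lateral
model; no robust (scenario-based) optimization; no variable-RBE biological
model (the constant-1.1 prescription scaling is metadata); no DICOM
import/export; the energy-layer partition rule at refinement is a
reasonable surrogate for published spot-selection algorithms, not a
reproduction of any particular one.
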