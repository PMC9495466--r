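---
title: "Cilia-driven flow over a wall: model, solver, and the five-case study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cilia-driven flow over a wall: model, solver, and the five-case study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaflow)
```

## The problem

Motile cilia lining the embryonic zebrafish brain ventricle beat with an
asymmetric, roughly planar stroke and drive a directional flow of
cerebrospinal fluid along the ventricle wall. At the relevant scales
(filament length $L \approx 4.75\,\mu$m, beat frequency $f \approx 30$ Hz,
tip speeds of a few hundred $\mu$m/s, water-like fluid) the Reynolds number
is $Re \sim 10^{-3}$: inertia is negligible and the flow at every instant is
fully determined by the instantaneous motion of the boundaries. `ciliaflow`
simulates this regime in two dimensions: one or two cilia, anchored to a
no-slip floor, beat with prescribed kinematics, and the package computes the
forces they exert on the fluid, the velocity field they generate, and the
volumetric flux they pump across a downstream cross-section.

The package ships five standard comparison cases — a single cilium whose
beat's spatial mean line is tilted 30°, 50° or 60° from the vertical, and a
pair of 60°-tilted cilia beating either in phase or half a cycle out of
phase — which probe the three experimental questions the geometry poses: how
tilt, cilium count, and phase relationship shape the pumped flow.

## Governing equations and the quasi-steady reduction

The fluid satisfies incompressible Navier–Stokes dynamics,
$\nabla\cdot\mathbf{v} = 0$ and
$\rho\,\partial_t\mathbf{v} + \rho(\mathbf{v}\cdot\nabla)\mathbf{v} =
\nabla\cdot\tau$, with $\rho = 1000$ kg/m³ and $\mu = 1$ cP. With
$U \approx 0.3$ mm/s and $L \approx 5\,\mu$m, $Re = \rho U L / \mu \approx
1.5\times10^{-3}$, and the viscous diffusion time across the
$25 \times 50\,\mu$m window ($\approx 2.5$ ms) is an order of magnitude
shorter than the 33 ms beat period. The solver therefore drops the unsteady
and advective terms and solves the Stokes equations afresh at each of the
330 timesteps (33 frames per cycle × 10 cycles, 1 ms each), with the
prescribed cilium node velocities as moving boundary conditions.

One deliberate consequence: in a quasi-steady solver every beat cycle
produces an identical flux pattern, so phenomena that build up over
successive cycles in a transient closed-box simulation — slowly growing
recirculation vortices, cycle-to-cycle increases in peak velocity — are
*not* reproduced. The package asserts this periodicity in its tests rather
than hiding it, and all cross-case comparisons are comparisons of the
converged within-cycle dynamics. Section "Known limitations" returns to what
this does to the two-cilium in-phase comparison.

## The boundary solver: regularized Stokeslets with an exact wall image

Cilia are zero-thickness moving boundaries, not elastic structures: the
force densities along them are Lagrange multipliers enforcing the prescribed
motion. The solver represents each cilium node (except the anchor) as a
regularized point force with blob
$$\phi_\varepsilon(r) = \frac{2\varepsilon^4}{\pi (r^2+\varepsilon^2)^3},$$
whose biharmonic potential has the simple closed form
$F(s) = (s+\varepsilon^2)\ln(s+\varepsilon^2)/16\pi$ with $s = r^2$.

The no-slip floor is built into the kernel rather than discretized. In two
dimensions the velocity of Stokes flow is the perpendicular gradient of a
stream function, and the stream function of a point force solves a
biharmonic equation with *clamped-plate* boundary conditions on a no-slip
wall ($\psi = \partial_y \psi = 0$ on $y=0$). For the half-plane the clamped
biharmonic Green's function admits an exact reflection formula, which
carries over verbatim to the regularized potential:
$$G(\mathbf{x};\boldsymbol{\xi}) = F(r^2) - F(\rho^2) + 4y\,\eta\,F'(\rho^2),$$
where $r$ is the distance to the source at height $\eta$ and $\rho$ the
distance to its mirror image. Three properties follow *identically*, not
approximately:

* **No slip:** $G$ and its normal derivative vanish on $y = 0$, so the
  velocity kernel is exactly zero on the wall.
* **Incompressibility:** velocities are perpendicular gradients of stream
  functions, so $\nabla\cdot\mathbf{v} \equiv 0$.
* **Reciprocity:** $G$ is symmetric in field and source point, so the
  mobility matrix is exactly symmetric (and, for admissible geometries,
  positive definite — dissipation $\sum \mathbf{f}\cdot\mathbf{v} \ge 0$).

The kernel expressions in `R/kernels.R` were generated from this potential
by a computer-algebra derivation and verified symbolically for all three
properties before being frozen into code; the test suite re-verifies them
numerically against central finite differences of $G$ implemented
independently in the test helpers. Because the free-space 2D Stokeslet grows
logarithmically, the wall treatment is what makes the far field decay
($\sim 1/r^2$ for a force near a wall) and the problem well-posed; it is
mandatory, not optional. A `collocation-strip` mode (free-space kernel plus
a strip of zero-velocity wall points) is retained purely as a cross-check
and agrees with the image system on cycle-mean fluxes to well under 2%.

At each timestep the mobility matrix $M$ maps the stacked point forces to
velocities at the collocation points; `solve_forces()` inverts
$M\mathbf{f} = \mathbf{v}$ directly (relative residual $\le 10^{-8}$
enforced), with a Tikhonov-regularized fallback, flagged in the diagnostics,
if conditioning ever demands it. The anchor node of each cilium lies *on*
the wall, where the wall kernel vanishes identically; its mobility row would
be zero and its force indeterminate, so anchors are excluded from the
collocation set — the wall itself already enforces zero velocity there.

Units are µm, s, Pa·s and pN/µm (force per unit out-of-plane depth); in
this system the kernel is dimensionless and scale-consistent (the mirror
combination cancels the logarithm's scale dependence exactly).

## The synthetic beat generator

No coordinates of the imaged beat are available, so the waveform module
generates a parametric stand-in with the documented gross features: length
4.75 µm, period 0.033 s, 20 nodes, 33 frames per cycle, a tiltable spatial
mean line, and a non-reciprocal stroke that pumps to the right. The shape
model is a tangent-angle wave
$$\theta(s,t) = \theta_0 + A\,\mathrm{ramp}(s)\,
  \big[\cos(ks)\cos(\omega t) + a\,\sin(ks)\sin(\omega t)\big],$$
integrated from the anchor as
$(x,y)(s) = \int_0^s (\sin\theta, \cos\theta)\,ds'$, evaluated at segment
midpoints so each frame's polyline has *exactly* the requested arc length.
The blend parameter $a \in [0,1]$ (`asymmetry`) interpolates between a
standing wave ($a=0$), which is exactly time-reversible — the frame sequence
is palindromic, giving an analytic scallop-theorem zero test — and a pure
traveling wave ($a=1$), the maximally non-reciprocal member of the family.
A pure traveling tangent-angle wave is *never* reciprocal, which is why the
reciprocity switch must live in the standing/traveling blend rather than in
an amplitude envelope. After integration the whole cycle is rigidly rotated
about the anchor so the pooled principal direction of the node cloud sits at
`base_tilt` exactly.

Defaults and rationale (all config-exposed, chosen once on kinematic
grounds):

| parameter    | default | why |
|--------------|---------|-----|
| `length`     | 4.75 µm | measured filament length |
| `frequency`  | 1/0.033 Hz ≈ 30.3 | the stated 0.033 s period, so 33 × 1 ms timesteps tile one cycle exactly |
| `n_nodes`, `n_frames` | 20, 33 | the study's discretization |
| `amplitude`  | 0.85 rad | tip sweep of roughly half the filament length, a whip-like ependymal beat |
| `wavenumber` | 0.45 rad/µm | ≈ 2 rad of phase lag base-to-tip: a visible but not flagellar curvature wave |
| `asymmetry`  | 0.8 | strongly non-reciprocal; pumps rightward under the sign conventions below |
| ramp         | 0.3 + 0.7 s/L | the base pivots less than the tip, keeping the near-base tangent above the floor at 60° tilt |

With these values the beat pumps in +X for every tilt in the study and all
nodes stay strictly above the floor up to (and a little beyond) the 60° tilt
at which the stroke grazes the wall — the physical reason the study caps
tilt at 60°. `apply_tilt()` refuses $|$tilt$| \ge 90°$ and warns above 60°.

What the generator does *not* emulate: the measured beat's exact curvature
profile, its stroke-speed asymmetry (power stroke faster than recovery), or
any cycle-to-cycle variability. Passing tests therefore demonstrate the
solver's correctness and the direction/ordering phenomenology of tilt and
phase, not quantitative agreement with any individual measured cilium.

## Observables

The metrics window is the $50 \times 25\,\mu$m rectangle (wall along the
long side). `flux_across_right_line()` integrates the horizontal velocity
over the right edge with Gauss–Legendre quadrature (32 nodes by default; the
integrand is smooth, so quadrature error is at machine precision — verified
against 10⁴-point trapezoid integration). `boundary_balance()` checks the
integral form of incompressibility over all four edges.
`aggregate_flux()` reduces the per-timestep series to per-cycle means, the
whole-run mean, and the *maximum per-cycle mean* — the interpretation used
for "maximum pumping rate", since per-cycle values are what the comparison
plots show; the instantaneous extrema are reported separately.

Mass flow rates need an out-of-plane depth, which a 2D model does not
define. The package's primary observable is therefore the volumetric flux
per unit depth (µm²/s); mass flow in µg/s is reported at an explicit,
config-set `reference_depth` (default 1 m, the convention planar commercial
solvers use), printed in every provenance block. At the defaults
(ρ = 1000 kg/m³, depth 1 m) the µg/s value coincides numerically with the
µm²/s value.

## Numerical choices

* **Regularization length** $\varepsilon$ defaults to the node spacing
  $L/(n_\text{nodes}-1) = 0.25\,\mu$m, matching the mesh scale of the
  original study. $\varepsilon$ is physically the hydrodynamic thickness of
  the filament: in 2D the drag per unit length depends on
  $1/\ln(\cdot/\varepsilon)$, so halving $\varepsilon$ changes forces by
  tens of percent. Refining the node count while tying $\varepsilon$ to the
  spacing is therefore *not* a convergent limit (measured: 31% flux change
  from 20 to 40 nodes), and even at fixed $\varepsilon$ the discrete force
  line approaches its continuum limit only logarithmically. Comparisons
  should always be made at a fixed $(n_\text{nodes}, \varepsilon)$ pair —
  as all five shipped cases are.
* **Velocities** by centered cyclic differences: second-order accurate,
  exactly periodic, exactly zero at the anchor.
* **Half-cycle phase offset** is $\lfloor 33/2 \rfloor = 16$ frames; 33 is
  odd, so an exact half cycle is unrepresentable on the frame grid and the
  frame grid is the beat's native resolution (no interpolation).
* **Two-cilium spacing** defaults to 5 µm (about one cilium length),
  anchors centred in the window; a single cilium sits at $x = 15\,\mu$m so
  the downstream structure fits in frame. Neither position is dictated by
  the geometry, so both are config-exposed and logged.
* **Near-contact handling:** inter-filament separations below $\varepsilon$
  are detected and logged with a warning, not prevented (prescribed
  kinematics cannot respond to contact anyway); collocation points closer
  than $\varepsilon/10$ are rejected as a conditioning error.
* **Degenerate inputs:** points below the wall are domain errors; a zero
  boundary-velocity vector returns exactly zero forces; `amplitude = 0`
  produces a static rod and an identically-zero flux series.

## Known limitations

* The quasi-steady solver cannot reproduce cycle-growing vortices or any
  "flux builds up over ten cycles" behaviour; per-cycle fluxes are provably
  identical, and the run aggregates collapse accordingly.
* **In-phase pair versus single cilium.** With identical prescribed
  kinematics in the Stokes limit, a pair's combined flux tends to the
  single-cilium value as the spacing shrinks to zero and grows toward twice
  it as the spacing widens; at the default 5 µm it pumps about 2.2× a single
  cilium, with ~25% mutual screening. A *reduction below a single cilium*,
  as transient closed-domain simulations have reported for synchronized
  pairs, has no mechanism in this limit — the package reports the screening
  ratio honestly instead. The out-of-phase pair robustly outpumps the
  in-phase pair, and tilt monotonicity (30° < 50° < 60°) holds.
* The open half-plane replaces zero-pressure outer boundaries; the
  rectangle is a metrics window only. Absolute flux magnitudes are
  therefore not comparable to closed-box solvers (and the µg/s scale is
  depth-convention dependent), while cross-case orderings are robust.
* Everything is planar: no out-of-plane recovery-stroke sweep, no 3D
  metachronal coordination, no cilium elasticity or flow-modified beating.

## Problem sizes used by the tests

The shipped test-and-acceptance configuration exercises the full default
study (five cases, 10 cycles × 33 frames, 19 collocation points per cilium)
— about 1 s per case on one core, since the periodic solves are cached
within a run — plus reduced geometries (6–20 random points) for the solver
oracles. Velocity-field grids in tests use 0.25 µm spacing where a contract
names it and coarser grids elsewhere; all fixtures are generated in code at
test time.

## A worked run

```{r, eval = FALSE}
suite <- run_case_suite()
suite[, c("case", "label", "mean_massflow_ug_s", "max_massflow_ug_s")]
```

prints one row per case with the pumping observables discussed above;
`run_scenario(build_case(3))` gives the full per-timestep series,
diagnostics (solver residual, wall slip, condition number) and an
end-of-cycle velocity field exportable with `write_field_vtk()`.
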