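---
title: "Methods: discrete multi-physics simulation of a flexible bicuspid valve"
author: "sphvalve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete multi-physics simulation of a flexible bicuspid valve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`sphvalve` couples three particle-based models in a single 2D domain:

* a weakly-compressible SPH (WCSPH) fluid for blood,
* a mass-spring-hinge (MSM) chain for each flexible valve leaflet, and
* an on-line liquid-to-solid phase-change algorithm that converts fluid
  particles into bonded solid "aggregate" particles (a calcification /
  clot analogue) and breaks those bonds again when the tension exceeds a
  threshold.

Everything is expressed through four particle kinds — `FLUID`, `WALL`,
`MEMBRANE`, `AGGREGATE` — stored in flat arrays indexed by id. A phase
change is an O(1) relabel plus a change in which force laws act on the
particle; the total particle count is invariant over a whole simulation.

# Fluid model

**Kernel.** 2D cubic spline with support radius $2h$ and
$h = 1.3\,s$ where $s$ is the lattice spacing. $W(0,h) = 10/(7\pi h^2)$
and the kernel integrates to one over the plane (checked numerically to
$10^{-4}$).

**Density.** Direct summation every step,
$\rho_i = \sum_j m_j W(r_{ij})$, including the self term. Wall, membrane
and aggregate particles participate as boundary neighbors (they carry a
density and a pressure), which provides the dominant part of the
no-penetration behavior through the pressure force.

**Equation of state.** Tait closure
$p = \frac{c_0^2 \rho_0}{\gamma}\left[(\rho/\rho_0)^\gamma - 1\right]$
with $\gamma = 7$. The sound speed is numerical, not physical: the
weak-compressibility contract asks for $c_0 \ge 10\,U_{max}$ so density
fluctuations stay below a few percent. The validated channel fixtures
honor this contract; the pulsatile valve scenario is discussed below.

**Momentum.** Symmetric pressure term
$-m_i m_j (p_i/\rho_i^2 + p_j/\rho_j^2)\nabla W$ plus the Morris laminar
viscosity operator with the physical dynamic viscosity
($\mu = 0.0035$ Pa s for blood, $\rho_0 = 1056$ kg m$^{-3}$). There is no
artificial viscosity. All pair terms are exactly antisymmetric, so the
net internal force vanishes to round-off; the integrator tracks this as a
diagnostic and the suite requires $\le 10^{-12}$ relative, every step.

**Forcing.** The pulsatile pressure gradient is imposed as a per-particle
acceleration $g(t) = g_0 \sin(2\pi f t)$ applied to `FLUID` particles
only (aggregates, being solids, do not receive it). A constant waveform
and an arbitrary direction are available for the validation fixtures
(steady channel flow, settling under gravity).

**Boundaries.** Periodic in $x$ (minimum-image convention everywhere,
including bonds that straddle the seam); rigid walls are three layers of
fixed SPH particles. A short-range Monaghan-type repulsion
$D[(r_c/r)^4 - (r_c/r)^2]$, cut at $r_c = s$ and capped below $0.3 r_c$,
acts between fluid and solid kinds as a no-penetration safety net and is
what gives the zero-thickness membrane its effective mechanical
thickness. Between fluid pairs a much gentler version (20 % strength,
cut at $0.5 r_c$) acts as a guard against the tensile pairing
instability of the cubic-spline kernel: it engages only well below the
equilibrium spacing, so a regular lattice never feels it. Non-bonded
solid pairs interact through the same repulsion when leaflet-leaflet
contact matters (enabled in the valve scene, where the closed leaflets
slide over each other).

**Integrator.** Kick-drift-kick (velocity-Verlet family) with
$\Delta t = 0.25\,h/(c_0 + U_{max})$, additionally bounded by the viscous
diffusion limit $0.125\,h^2\rho_0/\mu$. Spring and hinge forces are far
stiffer than the acoustic scale, so they are integrated with an inner
sub-stepped loop (RESPA-style): only particles that carry bonds or
hinges are sub-stepped, with the sub-step chosen from the stiffest
spring and the lightest solid particle; the SPH forces are held frozen
across the inner loop. Pair iteration order is deterministic, so runs
are bit-reproducible for a given configuration and RNG seed.

# Membrane model

Each leaflet is a chain of `MEMBRANE` particles joined by harmonic
springs (stiffness $k_b$, rest length $l_0$) and angular hinges
($U = \tfrac12 k_a(\theta - \theta_0)^2$, straight rest shape). The
mapping to continuum properties uses the discrete-beam equivalence

$$k_b = \frac{E\,d}{l_0}, \qquad k_a = \frac{E\,d^3}{12\,l_0}
  \;\Longrightarrow\; d = \sqrt{12 k_a/k_b},\quad F = k_a l_0,\quad
  E = k_b l_0 / d,$$

with $F = E d^3/12$ holding exactly (per unit out-of-plane width). This
convention is documented so users can recalibrate if they prefer a
different shell theory. Hinge forces are the analytic gradient of the
angular potential and are validated against finite differences; each
triplet conserves linear and angular momentum to $10^{-10}$.

The cantilever validation clamps a chain by anchoring its two root
particles and applies a transverse tip load. For the discrete chain the
exact tip compliance is $P l_0^3 (u^3/3 - u/12)/F$ with $u = n - 3/2$:
the continuum-equivalent clamp plane sits half a spacing behind the
first free hinge. The suite therefore compares against
$\delta = P L^3/(3F)$ with $L = (n - 3/2)\,l_0$ and requires agreement
within 5 % (measured: about 1 %).

# Scene geometry

The bicuspid valve scene is a periodic channel of half-thickness
$Z = 0.0125$ m with a circular chamber of radius $R = 0.0215$ m; the
membrane length is $L = 0.016$ m. The origin sits on the centerline at
the leaflet root plane; the chamber disk is centered at $(R, 0)$, so its
upstream rim is tangent to the root plane and the leaflets root at the
channel walls at the chamber entrance. The exact root placement is read
qualitatively from the study geometry and is configurable. The default
channel extends $6Z$ upstream and downstream of the chamber.

All particles sit on a square lattice of spacing $s$. Classification
uses the signed distance to the fluid region (channel strip union
chamber disk): fluid inside, walls in a band of `wall_layers` spacings
outside. Leaflets are initialized straight in the closed position, tips
one lattice spacing apart at the centerline; lattice sites within
$0.7 s$ of a leaflet (or $0.45 s$ for walls, at the roots) are left
empty so no particles coincide. Builders are deterministic: identical
inputs give bit-identical scenes.

# Aggregation algorithm

Growth is seeded either by explicit ids or by a shear-stress threshold.
Every $N$ steps each active seed collects the `FLUID` particles within
the capture radius $R_{max}$, visits them in (distance, id) order and
converts each with probability $p$ (one RNG draw per candidate, making
the stochasticity well-defined and reproducible). A conversion relabels
the particle `AGGREGATE`, creates one bond seed-to-particle with rest
length equal to the current separation (stress-free birth, avoiding
force discontinuities), and flags the new particle as a seed for the
next invocation. Bonds connect only a seed and a formerly-fluid
particle, never two existing aggregates, so the aggregate bond graph is
a forest by construction — fragmenting $b$ bonds always yields exactly
$b$ additional parts.

*Circular* mode keeps all seeds active (compact deposits that end up
surrounded); *filiform* mode deactivates seeds after one invocation and
caps conversions at one per seed, producing a thread that propagates
from its newest end. Conversion probabilities well above physical
nucleation rates are used deliberately to reach sizable aggregates in a
few forcing cycles, the usual timescale-compression device for slow
surface processes.

Fragmentation is checked every step (tension can spike between
aggregation invocations): every breakable bond whose tension
$k_b(|r| - r_0)$ exceeds the threshold (default $1.3\times10^{-7}$ N) is
removed in that step and logged. The default aggregate bond stiffness
places the break threshold at a 1 % strain of the capture radius so the
tension ramp toward breakup is resolved over many time steps rather
than crossed within one.

A practical note on scales: at blood viscosity, a relative flow of only
$\sim 4\times10^{-5}$ m s$^{-1}$ already produces a per-particle
hydrodynamic force of $1.3\times10^{-7}$ N. An aggregate bonded under
flowing conditions therefore fragments essentially immediately at this
threshold. The fragmentation study consequently grows the filiform
chain on the quiescent, pre-relaxed scene (every bond born stress-free,
all tensions exactly zero) and then switches the pulsatile forcing on;
tensions grow from zero at a fraction of the threshold per step, the
attachment bond (which carries the accumulated drag of the whole chain)
crosses first, and the first crossing splits the tree into exactly two
parts — one attached to the leaflet, one free.

# Dimensionless analysis

For a scenario with reference velocity $U$ (operationally: the largest
streamwise particle speed across a channel cross-section, taken over a
forcing cycle), the package computes

$$\mathrm{Re} = \frac{\rho U Z}{\mu},\qquad
  N_f = \frac{\rho f^2 d^5}{F/L},\qquad
  \Lambda = \frac{Z}{L},\qquad
  N_R = \mathrm{Re}\cdot N_f,$$

with $N_R = \mathrm{Re}\,N_f$ exact by construction. $F$ is used in
N m$^2$ (kg m$^3$ s$^{-2}$): that is the only unit assignment under
which $N_f$ is dimensionless, and the scenario sheets are interpreted
accordingly. Scenarios with equal $N_R$ are expected to show the same
type of membrane deformation even when Re, $N_f$, $f$ and $U$ differ
individually. The bundled scenario sheet contains some internally
inconsistent cells (rows whose printed Re does not follow from its own
inputs, and rows where $N_R \ne \mathrm{Re}\cdot N_f$); only the
self-consistent cells — the hard-membrane block and the
intermediate-simulations block — are used as worked references. The
equal-$N_R$ regime claim is documented here and illustrated by the
membrane-kinematics tooling rather than asserted as an automated test:
a meaningful two-run comparison at matched $N_R$ costs two full FSI
cycles and is dominated by the forcing-amplitude issue discussed next.

# The pulsatile scenario and its peak velocity

The study conditions pair a forcing amplitude $g_0 = 500$ m s$^{-2}$ at
$f = 1$ Hz with an expected peak channel velocity of $0.9$ m s$^{-1}$.
These two numbers are mutually inconsistent for a periodic channel: the
Womersley number is $\alpha = Z\sqrt{2\pi f \rho/\mu} \approx 17$, so
the flow is inertia-dominated and integrating the forcing over a half
period gives a free-stream velocity scale of
$g_0/(\pi f) \approx 160$ m s$^{-1}$ — two orders of magnitude above the
stated peak. Nor can the leaflets absorb the forcing: the trans-valve
pressure load at this amplitude ($\sim\rho g_0 L_x \approx 10^5$ Pa)
exceeds the bending resistance of a leaflet with $F = 0.056$ N m$^2$ by
several orders of magnitude. The coarse runs confirm both expectations:
the bulk accelerates at nearly the free-slug rate and trans-valve jets
reach many times the bulk speed.

The package runs the scenario exactly as specified and reports the peak
channel velocity measured in the window where the weakly-compressible
solution is still meaningful (all fluid speeds below the numerical sound
speed); `peak_velocity_scenario()` returns the peak, the extent of the
valid window and the full trace. At the coarse desk scale
($s = 10^{-3}$ m, $c_0 = 15$ m s$^{-1}$ — the upper end of the design
range, because the trans-valve jets far exceed the bulk velocity) the
measured peak is a few m s$^{-1}$ and the validity window closes well
before the forcing peak. This measured value is reported as-is; it does
not reproduce 0.9 m s$^{-1}$, and we flag the discrepancy as a property
of the stated conditions rather than of the discretization.

# Validation fixtures and problem sizes

The suite validates against closed-form oracles at sizes chosen for a
single CPU:

* **Poiseuille**: steady body-forced channel, $Z = 0.01$ m,
  $s = Z/10$ (760 fluid particles), generic fluid
  ($\rho = 1000$, $\mu = 0.1$, $c_0 = 0.05$) run for 3 s of simulated
  time (several viscous times). L2 profile error vs the analytic
  parabola: about 1.2 %, bound 5 %. Error decreases monotonically under
  lattice refinement ($Z/5 \to Z/10 \to Z/20$).
* **Womersley**: same channel, sinusoidal forcing at $\alpha = 3$, six
  periods, centerline amplitude vs the exact oscillating-channel
  solution: about 0.03 %, bound 10 %. The analytic series itself is
  cross-checked against an independent finite-difference integration of
  the 1D PDE to $10^{-4}$.
* **Cantilever**: 33-particle chain, soft-membrane constants
  ($F = 0.008$ N m$^2$, $d = 3\times10^{-4}$ m), tip load
  $10^{-3}$ N: deflection within about 1 % of Euler-Bernoulli.
* **Aggregation lattice**: unit lattice, single seed, $p = 1$:
  exactly 4 conversions at $R_{max} = 1.2$ and 8 at $1.5$, equal to a
  brute-force distance count; conversion rates at $p < 1$ sit within
  3$\sigma$ binomial bounds over 200 seeded repetitions.
* **Containment**: a settling fluid column never brings a fluid center
  within $0.4\,s$ of a wall particle over $10^4$ steps.

Density fluctuations stay below 3 % of $\rho_0$ and the internal-force
balance below $10^{-12}$ relative in all validated runs.

What the synthetic scenes do *not* emulate: 3D geometry and
out-of-plane leakage, non-Newtonian blood rheology, turbulence,
physiological pressure-flow coupling (the periodic body force is an
infinite-compliance pump), and any biochemistry of real thrombosis or
calcification. Passing tests demonstrate the numerical fidelity of the
discretization and the algorithmic contracts of the phase-change model,
not clinical realism.

# Qualitative features

With the leaflets held rigid and a gentle steady forcing through a
partially open valve, the flow develops the expected structure: net
forward flow through the valve, recirculation in the chamber bulge, and
a shear-stress maximum near — but not exactly at — the leaflet tips
(the acceptance suite checks the presence of these features without
asserting magnitudes). With flexible leaflets, soft membranes evert
under backflow while stiff membranes fail to open fully and lose tip
symmetry; circular aggregates seeded between the lower leaflet and the
wall progressively immobilize that leaflet. These flexible-leaflet and
aggregation behaviors are qualitative observations at the printed
forcing and are subject to the amplitude caveat above.

# Numerical choices and degenerate inputs

* Hinges at exactly straight configurations with a straight rest angle
  exert zero force; collinear arms with a non-straight rest angle are a
  fault (the angle gradient is undefined).
* Coincident interacting particles are a computation fault, not a
  silent NaN.
* Time steps beyond the CFL/viscous bound are rejected up front;
  non-finite state aborts a run with an error.
* The no-penetration force is capped below $0.3 r_c$ so a single
  violent approach cannot destabilize the integrator.
* Snapshot CSVs carry 17 significant digits and round-trip
  bit-identically; VTK legacy POLYDATA output is provided for standard
  visualization pipelines.
* Reproducibility: every stochastic element draws from R's RNG; a
  run configuration plus seed reproduces snapshots and event logs
  byte-for-byte.

# Known limitations

* 2D only; extrinsic quantities are per unit out-of-plane width.
* The WCSPH solution degrades sharply once local speeds approach the
  numerical sound speed; the pulsatile scenario at the stated amplitude
  leaves the weakly-compressible regime within a fraction of a cycle.
* The aggregate binding force is a plain harmonic bond; no
  strain-stiffening, no aggregate-aggregate fusion, no re-liquefaction.
* Hinges are not applied within aggregates (bonds only), so filiform
  clots are perfectly flexible threads.
* The fragmentation threshold of $1.3\times10^{-7}$ N is tiny relative
  to hydrodynamic per-particle forces at these flow scales (see the
  aggregation section); fragmentation studies should interpret it as an
  ordering device (which bond fails first) rather than a materials
  constant.
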