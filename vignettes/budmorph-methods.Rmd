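---
title: "The budmorph model: mechanics, signaling, and growth of a budding yeast surface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The budmorph model: mechanics, signaling, and growth of a budding yeast surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budmorph)
```

# Overview

`budmorph` simulates one budding cycle of *Saccharomyces cerevisiae* as the
interplay of three coupled processes on a closed triangulated surface
representing the combined cell wall and membrane:

1. **Surface mechanics.** The triangulated network is an elastic shell under
   constant turgor pressure, evolved by overdamped (first-order) dynamics.
2. **Chemical signaling.** Active Cdc42 obeys a reaction–diffusion equation
   on the deforming surface, with a well-mixed global inhibitor providing
   negative feedback; an external spatial cue biases where the polarized
   cluster forms.
3. **Surface remodeling.** New wall material is inserted periodically as
   triangle-pair splits inside the chemically eligible region, and the
   network topology is relaxed by Metropolis edge flips modeling cell-wall
   rearrangement.

One *simulation time frame* is: re-converge the chemistry on the current
geometry, perform one growth event, run the scheduled edge-swap attempts,
and relax the mechanics. The central question the scenario presets address
is when this loop produces a spherical bud (aspect ratio near 1) versus a
tubular bud (aspect ratio above 1.5), and what stabilizes the aspect ratio
of a tube while it keeps growing.

# Mechanical submodel

Vertices (nodes) carry positions $x_i$; each node moves by
$c\,\dot x_i = -\nabla_{x_i} E_{\mathrm{total}} + F_{\mathrm{turgor},i}$,
with friction coefficient $c$. The potential has four terms.

* **Stretching.** Every edge is a linear spring,
  $E = \sum \tfrac{k_s}{2}(L-L_0)^2$. Edges on the septin ring use the
  rescaled law $E = \sum \tfrac{k_s}{2L_0^2}(L-L_0)^2$, which makes the
  ring's resistance scale-free in its rest length and markedly stiffer for
  the short ring segments — the ring acts as a stiff collar at the bud
  neck.
* **Bending.** Every interior edge is a hinge,
  $E = \sum k_b\,(1-\cos(\theta-\theta_0))$, where $\theta$ is the unsigned
  angle between the unit normals of the two incident triangles.
* **Area resistance.** Every face resists area change harmonically,
  $E = \sum \tfrac{k_a}{2A_0}(A-A_0)^2$.
* **Self-avoidance.** Non-connected vertex pairs within range $L_m$
  interact through a Morse potential
  $E = \sum D_m\,(1-e^{-a_m(L-L_m)})^2$, zero at the range boundary and
  repulsive below it.

Turgor is a constant pressure $P$: each face contributes $P\,(A_f/3)\,
\hat n_f$ to each of its three vertices. Turgor is the only term that does
work against the elastic network; growth manifests as expansion because
inserted material raises rest quantities, letting pressure push the surface
outward.

Rest state ($L_0$, $\theta_0$, $A_0$) is stored **per element**, so
remodeling operations can assign new rest quantities locally.

## Parameter defaults

All quantities are dimensionless; the unit of length is the initial mother
radius. There is no canonical published coefficient set for this
dimensionless formulation, so the defaults below were chosen once to place
the model in the bud-emergence regime and are exposed in `mech_params()`:

| parameter | default | role |
|---|---|---|
| `c` | 1 | friction; sets the time unit |
| `ks` | mother 40, bud 60 | stretching stiffness (bud stiffer in stretch) |
| `kb` | mother 6, bud 2 | bending stiffness (bud softer in bending) |
| `ka` | 40 | area resistance |
| `Dm`, `am`, `Lm` | 0.5, 20, 0.12 | Morse depth, width, range (sub-edge-length) |
| `P` | 4 | turgor pressure, constant within one cycle |
| `dt` | 5e-4 | forward-Euler step |

The higher stretching-to-bending ratio in the bud than in the mother is the
regime in which a bud can emerge at all under uniform pressure; the
absolute magnitudes set how far from equilibrium a growth event drives the
surface before the next relaxation.

## Numerical integration

The overdamped equation is integrated by forward Euler. Two safeguards
matter in practice:

* **Displacement trust region.** A step never moves a vertex farther than
  `dmax` (default 0.01). Repeated splitting makes tip triangles small, and
  hinge stiffness grows like $1/h^2$ with element height $h$, so a fixed
  stable time step for the whole mesh would have to shrink as the tip
  refines. Capping per-step displacement shortens only the offending steps
  and leaves soft global modes integrated at full `dt`. With the cap, a
  step is always a positive multiple of the force direction, so the descent
  property at $P=0$ is preserved.
* **Automatic halving.** If positions still become non-finite the
  relaxation restarts from the frame's initial state with `dt/2`, up to
  four times.

The mechanical relaxation between growth events comes in two layers: an
optional `relax_per_swap` Euler steps interleaved after every swap attempt
(default 0; the presets use 4), and `relax_max_steps` run after the swap
batch (default 200; the presets use 100). With the interleaved layer on,
the scheduled swap count acts as the *relaxation clock* of a frame — 125
swap attempts per growth event give the surface five times the
rearrangement-plus-motion time of 25. These budgets are *model*
parameters, not merely numerical ones: the tubular regime exists only
when material is added faster than the surface equilibrates.

# Chemical signaling submodel

Active Cdc42 concentration $a$ lives on vertices of the surface $\Gamma$;
the inhibitor $b$ is a single well-mixed scalar:

$$\frac{\partial a}{\partial t} = D_c\,\Delta_\Gamma a
 + \frac{k_0}{1+(\beta u)^{-q}} + \frac{k_1}{1+(\gamma p a)^{-h}}
 - k_2 a - k_3 b a,\qquad
\frac{db}{dt} = k_4(\bar a - k_{ss})\,b,$$

with $p = 1/(1+(\beta u)^{-q})$ and $\bar a$ the area-weighted surface
average. The $b$ equation is integral feedback: any steady state with
$b>0$ has $\bar a = k_{ss}$ exactly, which pins the total amount of active
Cdc42 and thereby the size of the polarized patch, while the cue $u$ pins
its location. The package asserts this homeostasis after every frame's
solve.

The cue is a function of height along the bud axis (+z by convention):
$u = u_{\min} + (u_{\max}-u_{\min})\,\big((H_T-H_{\min})/H_{\mathrm{total}}\big)^{n(t)}$,
where $H_T$ is the face-centre z, and the normalization uses face-centre
extremes so the tip face carries exactly $u_{\max}$ and the bottom face
exactly $u_{\min}$. The exponent $n(t)$ controls gradient sharpness —
$n=2$ is a shallow, nearly quadratic profile, $n=8$ decays rapidly away
from the tip — and may follow a piecewise-linear schedule in the frame
index to model polarization that strengthens and then fades within one
cycle.

## Discretization

Fields live on vertices. The Laplace–Beltrami operator is the standard
cotangent finite-element weak form with barycentric lumped masses; the
operator is symmetric with zero row sums, constants are in its kernel, and
the $l=1$ spherical-harmonic eigenvalue is reproduced within 2% at mesh
subdivision 5 (with errors decreasing under refinement; both are asserted
in the test suite). Cotangents of corner angles below $10^{-3}$ rad are
clamped with a warning. The face-based cue is mass-averaged to vertices
for the reaction terms; the face-level cue is used directly for growth
eligibility. $(\beta u)^{-q}$ is evaluated as $\exp(-q\log\beta u)$ with
$u$ clamped at $10^{-12}$; configurations must use $u_{\min}>0$.

## Time stepping and the quasi-steady solve

Each frame fully re-converges the chemistry on the frozen current geometry
(quasi-steady coupling; chemical kinetics are fast relative to growth).
One step of the activator applies, in order: explicit production terms,
backward-Euler diffusion (one sparse Cholesky factorization per frame,
reused across iterations), and the exact exponential factor
$e^{-\Delta t\,(k_2+k_3 b)}$ for the linear inactivation. Every substep
maps non-negative fields to non-negative fields, so the scheme is
unconditionally stable and needs no clipping. A fully explicit treatment
of the reactions is *not* stable here: at quasi-steady state $b$ reaches
order 10, so $\Delta t\,(k_2+k_3b)$ exceeds the explicit stability bound
and produces a period-2 oscillation that the non-negativity clip rectifies
into runaway growth of $b$. The inhibitor update multiplies $b$ by
$1+\Delta t\,k_4(\bar a - k_{ss})$ clamped to $[1/2, 2]$ per step; the
clamp tames the integral controller far from equilibrium and does not move
its fixed point.

Signaling defaults (`signaling_params()`): $D_c=0.1$, $k_0=1$, $k_1=1$,
$k_2=1$, $k_3=2$, $k_4=40$, $k_{ss}=0.02$, $\beta=2$, $\gamma=5$, $q=4$,
$h=2$, $\Delta t_{\mathrm{chem}}=0.1$. They were calibrated once against
two regime criteria on budded test geometries of increasing bud height:
with the shallow cue ($n=2$) the whole bud must exceed the eligibility
threshold (so insertion is spread and the bud stays spherical), while with
the sharp cue ($n=8$) eligibility must shrink to the tip neighbourhood as
the bud elongates. The diffusion length $\sqrt{D_c/(k_2+k_3b)}$ is what
smooths the activator across a shallow-cue bud; $q$ and $\beta$ set how
hard the cue response saturates.

# Remodeling

**Growth events.** A face is *eligible* when its mean vertex concentration
is at least `threshold_fraction` (default 0.8) of the maximum vertex
concentration on the bud; mother faces are never eligible. Each frame,
`insertions_per_event` edges are drawn uniformly at random among the
interior edges of the eligible region and split: a new vertex appears at
the edge midpoint (optionally offset slightly outward to avoid a coplanar
start), two triangles become four. New elements take rest quantities from
the current geometry scaled by `rest_growth_factor` (default 1.4) — this
is the material insertion. A constant number of insertions per frame
yields linear bud-area growth by construction, which the test suite
verifies as an ordinary-least-squares fit with $R^2>0.99$. Candidate
edges must be at least `min_split_frac` (default 0.4) of the mesh-wide
mean rest length: without this feature-size floor, repeated splitting
inside a small tip region refines triangles without bound until they
degenerate. Septin-ring edges are never split.

The rest dihedral of newly inserted hinges is a modelling choice exposed
as `rest_dihedral`. With `"current"`, deposited material adopts the local
curvature, so grown shapes are remembered and sit at an energy minimum —
no amount of remodeling rounds them. With `"flat"`, new wall carries no
intrinsic curvature, so bending supplies a genuine annealing drive toward
the equilibrium (spherical) shape, and morphology becomes a live
competition between spatially biased insertion and relaxation. All
scenario presets use the flat-rest rule (with swaps restricted to the bud
at annealing temperature `kT = 0.2` and four interleaved mechanics steps
per swap attempt), because that competition is precisely what the
experiments probe; `"current"` remains available for configurations that
want purely insertion-controlled morphology.

**Edge swaps.** A swap proposes replacing the shared edge of two adjacent
triangles by the opposite diagonal of their quadrilateral, modeling local
cell-wall rearrangement. Moves that would create a duplicate edge, drop a
vertex below valence 3, touch the septin ring, or create a degenerate face
are rejected outright. Legal moves are accepted with the Metropolis
probability $\min(1, e^{-\Delta E/k_T})$, where $\Delta E$ is the local
energy change *including* the rest-state reassignment of the flipped edge
(new rest length = mean of the four boundary rest lengths; the two face
rest areas are rescaled to preserve their summed rest area, conserving the
inserted material budget; the new hinge's rest angle is its current
angle). The local $\Delta E$ equals the global energy difference to
machine precision, which the tests assert. Swap attempts are drawn
uniformly over the whole surface by default (`swap_domain = "bud"`
restricts them; the presets restrict them, since the cell wall
rearrangement of interest happens over the bud surface). The temperature
controls how aggressively the network anneals: the presets use
$k_T = 0.2$, at which roughly a sixth of proposals accept, so the swap
count per frame is the operative relaxation dial; at $k_T = 0$ the
dynamics are pure descent.

# Shape metrics

* **Bud area**: sum of bud-face areas.
* **Aspect ratio**: by default, extents of the bud vertex cloud along its
  principal axes (largest over smallest); rotation and scale invariant.
  For perfectly axisymmetric clouds the principal directions within the
  degenerate subspace are arbitrary, which perturbs the extents at the
  per-mille level; real bud clouds are never exactly symmetric. A
  secondary height-over-width estimator (tip height above the neck plane
  over the maximal transverse diameter) is reported alongside.
* **Polarization height (PH)**: z-distance from the bud tip to the lowest
  bud vertex whose concentration reaches 0.8 of the bud maximum; relative
  PH divides by the tip-to-neck height and is clipped to [0, 1]. The
  threshold comparison is `>=`, so a uniform field gives relative PH 1.
* **Linear growth fit**: ordinary least squares of area against frame.

# Scenario presets

`fig3_n2` and `fig3_n8` run the fully coupled loop for 160 frames at mesh
subdivision 3 (642 initial vertices, initial bud cap 0.35 rad, 50 swap
attempts per frame), differing only in the cue exponent.
`fig4_es25/75/125` pin the growth region to a constant-size footprint of
the 30 bud faces nearest the tip (signaling bypassed) and vary only the
number of swap attempts per frame; `fig4_schedule150/100` switch 25 to 50
swaps late in the run. `fig5_case1/case2` drive the coupled loop with a
piecewise-linear $n(t)$ that ramps 5 to 12 and then decays to 7, case 2
decaying twice as slowly; the ramp peak sits at frame 50 of 160, the
decays end at frames 100 and 150 respectively, preserving the 1:2
proportion between the two decay durations.

These problem sizes (subdivision 3, 160 frames, 4 insertions per frame)
are the package's standard study conditions; the acceptance script runs
them unchanged over three seeds.

# What the scenarios do and do not emulate

The simulations reproduce the *qualitative* morphogenetic regimes —
spherical versus tubular budding as a function of cue sharpness, the
equilibrium-versus-growth competition controlled by swap counts, and
aspect-ratio stabilization under a decaying cue — on a coarse-grained,
dimensionless surface. They do not emulate: absolute sizes or times of
real cells (a config-level scale pair maps length to microns and frames
to minutes for plotting only), cytoplasmic or volumetric mechanics,
osmotic feedback on turgor, septin recruitment dynamics or ring
remodeling, competition between multiple Cdc42 clusters (a single cue
determines one site), actin-mediated transport, or cytokinesis. Passing
tests therefore support the internal consistency of the model and the
reproducibility of its regimes, not quantitative agreement with any
particular microscopy dataset.

# Known limitations

* The aspect ratio of the early bud (a shallow spherical cap) is large
  under the principal-axis estimator because the cloud is thin; it becomes
  meaningful once the bud has inflated. Endpoint comparisons use final
  frames.
* The quasi-steady solver can fail to converge when the geometry makes the
  homeostatic set point unreachable (the achievable surface average falls
  below `kss` as the polarized patch becomes a vanishing fraction of a
  long tube); the state is then flagged and the run continues with the
  best available field.
* Forward Euler plus trust region is robust but first-order; energies
  reported during a frame are those of the non-equilibrated surface by
  design.
* Edge identity is rebuilt after splits; code holding edge indices across
  a split must re-derive them (flips preserve indices).
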