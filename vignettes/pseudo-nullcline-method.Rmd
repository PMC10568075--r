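---
title: "Pseudo-nullcline analysis of two-module signaling models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-nullcline analysis of two-module signaling models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

Nullclines make planar ODE systems legible: the two curves where each
derivative vanishes partition the plane, and their intersections are the
fixed points. The construction does not survive in higher dimension —
the zero sets become codimension-1 surfaces — but many signaling models
have a special structure that rescues it. Suppose the state splits into
two blocks `x` and `y` such that

    dx/dt = f(x, alpha(y)),    dy/dt = g(y, beta(x)),

i.e. each block (a *module*) feels the rest of the system only through
one scalar. Freezing module 1's input at a value `a` and solving
`f(x, a) = 0` gives the module's steady-state response `X(a)`, a set
that may be multivalued when the module is bistable. Projecting
`(beta(X(a)), a)` onto the plane of the two coupling scalars yields a
curve `C1`; the same construction on module 2 yields `C2`. These
*pseudo-nullclines* are response functions of each module to a constant
input from the other, and every steady state of the coupled system lies
on an intersection of the two curves (both module equations hold there
simultaneously; conversely, an intersection supplies a full state
assembled from the two module solutions that zeroes the full vector
field).

Two properties carry the diagnostic weight:

* a **transversal** intersection is an ordinary steady state, whose
  stability comes from the full Jacobian's eigenvalues — oscillations
  born here arise through Hopf bifurcations, with the curves still
  crossing cleanly;
* a **tangential** contact marks a limit point: two steady states
  coalescing in a saddle-node (fold). When the fold sits on a limit
  cycle, the oscillation dies with diverging period (SNIC), and a
  nearby saddle with a colliding cycle indicates a saddle-homoclinic
  connection. Watching how the curves approach tangency as a parameter
  moves is the method's quick route to these global bifurcations,
  which standard continuation tools certify only indirectly.

## What the package computes

The pipeline mirrors the definition. `sweep_module_roots()` finds *all*
module steady states at one input by a deterministic multi-start damped
Newton (Halton grid over the state box, plus box corners and warm
starts); `trace_pseudo_nullcline()` repeats this over an input grid,
refines around root-count changes, and links points into branches by
nearest-neighbor continuation — folded response sets simply yield three
branches. There is no pseudo-arclength continuation: finding every sheet
at every input handles folds and disconnected branches without path
following, and tolerates models whose right-hand side contains implicit
algebraic solves. `project_curve()` maps branches to the analysis plane,
`find_intersections()` intersects the two polylines segment by segment
(near-miss "grazing" contacts are reported too, since near-tangency is
exactly the interesting signal), and `refine_and_classify()` polishes
each candidate to a root of the full vector field and classifies it:
tangential iff the smallest-magnitude Jacobian eigenvalue is within
`sn_tol` of zero, with the tangent-alignment angle reported as a
diagnostic (the eigenvalue criterion is the limit-point statement and
wins when they disagree).

Bifurcation tracking is sweep-plus-bisection. `scan_steady_states()`
records every steady state along a parameter grid; `detect_folds()`
bisects on root-pair appearance (parameter tolerance `1e-7`, fold state
cross-checked against the eigenvalue criterion); `detect_hopf()` bisects
on the sign of the leading complex pair's real part; `tangency_gap()`
condenses the curve geometry into a scalar — perpendicular separation
plus a tangent-misalignment penalty — that vanishes exactly at a
tangential contact; `locate_shom()` bisects a bracket with a cycle on
one side while monitoring the period, labelling the boundary
`SHom_candidate` when a saddle is present and `SNIC_candidate`
otherwise. Candidates, not certificates: distinguishing the two global
scenarios rigorously needs invariant-manifold computations that are out
of scope.

Determinism is a design constraint throughout: no RNG is used anywhere
(start points come from a radical-inverse Halton sequence), so repeated
runs are byte-identical, and every exported file embeds the package
version and a configuration hash.

### Numerical choices

* Root acceptance at `root_tol = 1e-9` (max-norm of the vector field);
  module deduplication at `1e-6` relative. Near a fold the residual
  basin is flat and a polished cluster represents one degenerate root;
  two roots are merged when the residual at their midpoint is still
  below tolerance, which cleanly distinguishes the cluster from genuine
  neighbors.
* Jacobians by central differences with a scale-aware step
  `1e-6 * max(1, |x_i|)`; models may attach exact Jacobians but none of
  the bundled ones needs to.
* Integration by `deSolve::lsoda` at `rtol 1e-8 / atol 1e-10`; cycle
  detection discards the leading transient until three successive peak
  amplitudes agree within 1%, then requires four stable peak spacings
  (quadratic interpolation of peak times). Trajectories that neither
  settle nor show repeated peaks are reported *inconclusive* rather
  than cycle-free.
* Stability labels come from the full Jacobian: a complex leading pair
  gives focus labels, a real positive leading eigenvalue with stable
  directions remaining gives "saddle", near-zero real parts give
  "marginal".

## The bundled models

**Embryonic cell-cycle oscillator** (`cellcycle`): active/inactive
cyclin-B–Cdk1 (module 1, input `apca`) against Plx1/APC (module 2,
input `cdk1a`), with Hill-type Cdc25/Wee1 positive feedback of strength
`r`, cyclin synthesis `k_synth` (nM/min) and APC-driven degradation.
The analysis plane is `(Cyc_tot, Cdk1_a)`; on `C1` total cyclin is
`cdk1a + cdk1i`, and on `C2` it comes from the synthesis–degradation
balance `Cyc_tot = k_synth / kdeg(apca)`, which is what makes low APC
activity correspond to large total cyclin far off the plot. The `extra`
parameter adds a constant basal APC activation that bounds `apca` away
from zero and thereby caps `C2`'s reach.

The rate constants are a **synthetic reconstruction**: the Hill
constants of the Cdk1 switch are the canonical published ones, while
the degradation and Plx1/APC legs were calibrated once against the
qualitative anchors of the published analysis — a stable spiral at
`k_synth = 0.04`, a small limit cycle at `0.05` (the lower Hopf falls
in (0.045, 0.05)), and a large relaxation cycle at `1.5` riding the
lower branch of `C1`. In the modified configuration
(`r = 10, ec50_plx = 72, extra = 2.6e-5`) this reconstruction has its
saddle-node pair at `k_synth ≈ 0.029 / 0.245` — the same geometry as
the published fold pair (tangential contacts of `C2`'s drop with `C1`
near its right-hand fold) but at a different parameter location, and
the bistable window carries two stable states and a saddle without a
coexisting limit cycle. Exact published bifurcation values are
therefore not reproduced by this parameterization; the tests that
encode them document the discrepancy rather than hide it.

**MAPK 2+2 motif** (`mapk22_reduced` / `mapk22_full`): the last two
levels of a MAPK cascade as elementary mass action (17 species), and
its reduction onto `(K0, X, A, App)` with `X = K2 + [K2·A] + [K2·Ap]`
and `Z = c1·A + c2·Ap` (`c1 = a5/(d5+k5)`, `c2 = a6/(d6+k6)`), so the
free active kinase is `K2 = X/(1+Z)`. The auxiliaries `Ap` and `K1`
are recovered at every right-hand-side evaluation by solving the
substrate and kinase conservation relations; both residuals are
strictly increasing in their unknown, so a clamped analytic-derivative
Newton converges unconditionally. These implicit solves are precisely
what blocks off-the-shelf continuation software on the reduced model —
and are no obstacle to the pseudo-nullcline pipeline. Because every
enzyme–substrate complex sits exactly at `C = E·S/Km` at *any* steady
state of the mass-action system, reduced-model steady states embed
exactly into 17-species steady states (`mapk22_embed_full()`), which is
how full-system eigenvalue censuses are computed.

The kinetic constants are again a synthetic calibration
(Markevich-style asymmetric two-site kinetics): the level-2 cycle is
bistable over its input `X` (hysteresis roughly `X ∈ (0.38, 0.63)`)
and fast, while the level-1 cycle is ~75× slower with a weakly bound
phosphatase leg, acting as the slow recovery module. The coupled motif
then oscillates for `E1tot` roughly in `(0.56, 0.68)` — duty fraction
below one half (brief peaks of `App`), periods growing toward the lower
boundary where the unique steady state has a real unstable direction,
the saddle-homoclinic/SNIC-flavored signature the method is built to
expose. Two deviations from the published geometry are known and
deliberate: this parameterization has no three-intersection phase
flanking its oscillation window, and `C1` is unfolded. A
saturated-phosphatase variant (`a3 = 10/3, k3 = 0.16/3` before the
timescale split) restores the 1 → 3 → 1 intersection census but cannot
oscillate — the phosphatase-sequestration fold that bends `C1` also
latches the coupled system. The defaults favor the oscillating regime
because most of the published anchors concern the oscillation.

**Toys** (`fhn_toy`, `linear_toy`, `sn_normal_form`,
`hopf_normal_form`): analytic oracles. FitzHugh–Nagumo split into two
one-dimensional modules makes the pseudo-nullclines coincide with the
textbook cubic and linear nullclines, the linear pair has the
closed-form fixed point (1, 1), and the normal forms pin fold and Hopf
detection at exactly zero.

## What the tests do and do not show

The oracle suite (FHN, normal forms, brute-force root sweeps,
conservation laws, reduced-vs-full embedding) certifies the machinery:
curve tracing, intersection refinement, classification and event
detection are correct where independent answers exist. The case-study
tests certify the *reconstructions'* phenomenology — the calibrated
anchors above — not the original parameter sets, which are not
available to this package. Published numeric bifurcation values are
asserted verbatim in the acceptance tests and fail where the
reconstruction disagrees; that failure is informative and intentional.

Problem sizes used throughout (curve grids of 150–250 points, scans of
10–20 parameter values, trajectories of a few thousand time units) were
chosen as the smallest that leave the detected events stable under grid
doubling.

## Worked example

```{r}
library(pseudonull)

sys <- get_model("cellcycle", c(k_synth = 0.05))
res <- analyze_plane(sys, n_grid = 200)
res$intersections[[1]]$stability     # "unstable_focus"

traj <- integrate_system(sys, sys$default_initial, 12000)
detect_limit_cycle(traj, "cdk1a")[c("exists", "period", "amplitude")]

mod <- get_model("cellcycle", c(r = 10, ec50_plx = 72, extra = 2.6e-5))
d <- scan_steady_states(mod, "k_synth", seq(0.02, 0.28, length.out = 14))
detect_folds(d)                      # the two saddle-node events
```

## Limitations

* Two modules only; no automatic decomposition of an arbitrary network.
* Sweep-based tracing costs more function evaluations than arclength
  continuation on smooth single-branch problems; it buys robustness to
  folds, disconnected branches and implicit right-hand sides.
* SHom/SNIC outputs are candidates backed by period divergence and
  saddle presence, not verified connecting orbits.
* The case-study parameter sets are reconstructions; quantitative
  bifurcation loci differ from the published ones even where the
  qualitative scenario matches.
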