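---
title: "Biphasic microvascular flow and inverse diameter adaptation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biphasic microvascular flow and inverse diameter adaptation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During functional hyperaemia the brain locally up-regulates blood flow:
neuronal activity in, say, one barrel of the somatosensory cortex is met
by a confined increase of perfusion in the corresponding patch of the
capillary bed. Which vessels change their diameters, and by how much, to
produce such a confined increase is hard to measure — the changes are of
the order of a few percent of a 4–5 µm capillary. `vasoadapt` addresses
the question from the purely fluid-dynamical side: it *solves the inverse
problem*. Given a microvascular network, an activated vessel set and a
target flow increase (e.g. +30 %), it computes per-vessel relative
diameter changes that reach the target while disturbing the rest of the
network as little as possible.

## Forward model

Blood is treated as a biphasic fluid: plasma plus individually tracked
red blood cells (RBCs). The network is a graph of straight pipe segments.
At every time step the flow rate in edge $e_{ij}$ is Poiseuille flow,

$$q_{ij} = T_{ij}\,(p_i - p_j), \qquad
  T_{ij} = \frac{\pi d_{ij}^4}{128\, l_{ij}\, \mu_p\, \mu_{rel,ij}},$$

where the relative apparent viscosity $\mu_{rel}(H_t, d)$ carries the
Fåhraeus–Lindqvist effect through the classic in-vitro empirical law.
The tube haematocrit $H_t$ of an edge is the volume fraction of the RBCs
it currently holds, $H_t = n_{rbc} V_{rbc} / (\tfrac{\pi}{4} d^2 l)$, so
the discrete cells dynamically modulate the flow resistances. Mass
balance at every interior node yields a sparse symmetric linear system
for the nodal pressures; fixed-pressure (Dirichlet) boundary rows are
eliminated symmetrically, and the reduced system is solved by sparse
Cholesky factorization with the symbolic analysis cached across steps.
The contract is the residual bound (interior imbalance below
$10^{-12}\max|q|$), not the particular solver.

RBCs advect along their edge with the cell velocity
$v_{rbc} = \frac{q}{A}\,\frac{H_d}{H_t}$, where the discharge
haematocrit $H_d \ge H_t$ follows from the Fåhraeus relation (cells
travel faster than plasma; the ratio has the analytic limit $1/r(d)$ as
$H_t \to 0$). At a divergent bifurcation a cell picks a daughter vessel
by sampling the empirical phase-separation (logit) law, which
preferentially sends cells into the faster, wider daughter; convergent
junctions and pass-throughs are deterministic.

Model and numerical choices worth knowing:

* **Units.** µm, ms, Pa, fL throughout; viscosity in Pa·ms (numerically
  mPa·s). Plasma viscosity defaults to 1.2 mPa·s, RBC volume to 49 fL
  (mouse); both are configurable in `rheology_params()`.
* **Viscosity argument.** The apparent-viscosity law is evaluated with
  the *tube* haematocrit by default, matching the forward model's stated
  coupling; a switch (`viscosity_haematocrit = "discharge"`) evaluates it
  with $H_d$ instead, documenting the ambiguity in how the original law
  was fitted.
* **Injection.** Each inflow boundary maintains a fractional
  accumulator incremented by $|v_{rbc}|\,\Delta t$ times the target
  linear cell density for the prescribed inflow tube haematocrit
  (default $H_{t,in} = 0.3$); one cell is injected at the entry end each
  time it exceeds one. This is deterministic given the flow history and
  reproduces $H_{t,in}$ in long-run average without Poisson clumping.
* **Packing rule.** Cells are points and do not exclude volume along an
  edge, but a cell never *enters* an edge that already holds the warning
  cap (default $H_t = 0.9$) worth of cell volume; it is rerouted to a
  free daughter or stalls at the junction. Without this rule cells
  accumulate without bound in near-zero-flow edges, where the viscosity
  feedback at capillary diameters is far too weak to stop them, and the
  haematocrit leaves the physical range. The rule only affects edges
  that are essentially stagnant.
* **Junction crossing.** A cell crosses at most one junction per step;
  residual travel continues in the receiving edge at that edge's current
  velocity. With the default $\Delta t = 0.4$ ms and capillary
  velocities of 0.5–1 µm/ms, a cell covers well under 1 % of an edge
  length per step, so multi-junction hops are negligible.
* **Degenerate cases.** Zero-flow edges stall their cells (a later flow
  reversal moves them back out). Bifurcations with more than two outflow
  daughters are handled by applying the two-daughter law pairwise,
  pooling the remainder at the diameter of its largest member — the
  empirical law is defined for two daughters only, and degree-3
  honeycomb networks never hit this path.
* **Viscosity domain.** The empirical law is evaluated at
  $\min(H_t, 0.95)$; with the packing rule active this cap is
  unreachable.

## Time averaging and the representative system

Because the tracked cells make $q$ and $p$ fluctuate, the inverse
problem is posed for statistically stationary fields: window means
$\langle q \rangle, \langle p \rangle, \langle b \rangle$ over
$N_{\Delta t}$ steps (default 500). A *representative transmissibility*

$$\tilde T_{ij} = \frac{\langle q_{ij}\rangle}
                       {\langle p_i\rangle - \langle p_j\rangle}$$

makes the averaged fields satisfy a deterministic linear flow-balance
system $\tilde A \langle p \rangle = \langle b \rangle$ exactly. Where
the averaged pressure drop falls below $\eta$ times the boundary
pressure scale (default $\eta = 10^{-8}$), or where the ratio comes out
non-positive (an averaging-noise artefact), $\tilde T$ falls back to the
window mean of the instantaneous transmissibility. A representative
viscosity $\tilde\mu_{rel} = \pi d^4 / (128\, l\, \mu_p \tilde T)$
inverts Poiseuille's law at the averaged state.

## The inverse problem

The parameters are relative diameters $\alpha_{ij} = d_{ij}/d^0_{ij}$ on
the adaptable edges. The cost is

$$J = \underbrace{\left(\frac{\bar q_{sim} - \bar q_{tar}}
    {\bar q_{tar}}\right)^2}_{\text{I: reach the target}}
  \;+\; \epsilon\,\underbrace{(\rho - \rho_{min})^2}_{\text{II: stay
    close to baseline elsewhere}}$$

with $\bar q_{sim}$ the length-weighted, direction-signed mean of
$\langle q\rangle$ over the activated edges (directions frozen at
baseline) and $\rho$ the Euclidean norm of the flow changes outside the
activated set, normalized by the target. The gradient
$dJ/d\alpha$ is assembled analytically: the only approximation is
$\partial\tilde\mu_{rel}/\partial\alpha \approx 0$, giving
$\partial\tilde T/\partial\alpha = \pi d^{0,4} \alpha^3 /(32\, l\, \mu_p
\tilde\mu_{rel})$ — always of the correct sign, so it affects the
convergence rate, not the solution. One adjoint solve (the transpose of
the symmetric reduced system, i.e. the same factorization) replaces the
$N_\alpha$ finite differences a naive gradient would need, which is what
makes networks with thousands of adaptable vessels tractable.

The driver alternates forward averaging windows with plain gradient
steps $\alpha \leftarrow \alpha - \gamma\, dJ/d\alpha$, clipped to
bounds when configured (e.g. ±15 %) and floored at $\alpha = 0.05$
(vessels cannot vanish). It has two phases:

1. **Phase 1** (primary target only, $\epsilon = 0$) runs until the
   *filtered* cost falls below `tol` (default $10^{-5}$, i.e. < 0.32 %
   flow discrepancy).
2. **Phase 2** activates the secondary term ($\epsilon = 1$ by
   default), sets $\rho_{min}$ to `rho_factor` (default 0.7) times the
   phase-1 $\rho$, and after each reconvergence reduces $\rho_{min}$
   geometrically by the same factor. When a level fails to reconverge
   within `level_budget` iterations the previous (feasible) state is
   restored and the driver stops: the minimal feasible $\rho_{min}$ has
   been bracketed.

Design choices in the driver, made where the procedure is genuinely
open:

* **Filtering before squaring.** Convergence is detected on the cost
  evaluated at *window-filtered* flow statistics (moving averages of
  $\bar q_{sim}$ and $\rho$ over `filter_window` iterations, default
  10), not on the moving average of $J$ itself. Averaging the quadratic
  directly leaves a variance floor of order the squared noise of a
  single window, which a tight tolerance cannot tell apart from a real
  target mismatch; filtering the statistic first removes that floor.
  Convergence is only declared on a full window, so a rising transient
  cannot cancel against an overshoot. The raw per-window $J$ is logged
  alongside.
* **Step size.** $\gamma$ is set so that the first update changes the
  largest-gradient $\alpha$ by `step0` (default 0.02), and is re-derived
  once when phase 2 activates — the secondary term changes the gradient
  scale by orders of magnitude, and a step calibrated on phase-1
  gradients overshoots badly. An explicit `gamma` overrides both.
* **Secondary reconvergence band.** A phase-2 level counts as
  reconverged when term I is below `tol` *and* the filtered $\rho$ lies
  within `rho_tol_rel` (default 2 %) of $\rho_{min}$. The norm over all
  non-activated edges carries measurement noise that an absolute squared
  tolerance cannot resolve; a relative band is discriminative against
  the 30 % per-level reduction while robust to that noise.
* **Baseline directions.** Edges with exactly zero baseline mean flow
  get $dir^0 = +1$ along the stored orientation, with a warning.

## The hexagonal test bed

`build_hexagonal_network()` generates the artificial capillary lattice
used throughout the package's tests: honeycomb cells whose sides are
vessels of uniform $d^0 = 4.5$ µm and $l = 75$ µm (the mean capillary
geometry of mouse cortex), one constant-pressure inlet and outlet on
opposite lattice sides, and a prescribed inflow tube haematocrit of 0.3.
The activated region is the 30 edges closest to the lattice centroid.
Lattice size and boundary pressures are free parameters of the
generator; the defaults — 9 × 9 cells (278 edges) and an 8000 Pa
pressure drop — were chosen once so that the activated region sits at
least three adjacency generations from any boundary and baseline RBC
velocities in the central region are ~0.5–1 mm/s (0.52 mm/s measured),
typical of cortical capillaries. Before any averaging window the cell
population is seeded uniformly at $H_t = 0.3$ and spun up (default 1000
steps) towards statistical stationarity.

What the generator does *not* emulate: the tortuosity, diameter and
length heterogeneity, vessel-type hierarchy (arterioles/venules), and
multi-scale boundary conditions of a real cortical network. Passing
tests on the lattice therefore validate the machinery — conservation,
the empirical laws, the adjoint gradient, the two-phase driver — not
claims about real vasculature; analyses on user-supplied realistic
networks go through the same tabular reader.

## Problem sizes used in tests

The shipped test-suite and the acceptance script run the full inverse
problem on the 9 × 9 lattice (198 nodes, 278 edges, ~1900 tracked
cells) with $N_{\Delta t} = 500$ and averaging windows identical to the
baseline window — sizes at which a complete two-phase inversion takes a
few minutes on one core. Gradient-correctness checks run on ≤ 20-edge
random networks against dense finite-difference oracles; closed-form
checks (single-vessel inversion, resistance identities) are instant.

## Known limitations

* No oxygen transport, vessel compliance, pulsatility, or transcellular
  signalling; the regime is low Reynolds/Womersley throughout.
* Only diameters adapt. The adjoint machinery would extend to boundary
  pressures or lengths, and the architecture does not preclude it, but
  no such parameters are exposed.
* The inverse problem is ill-posed; the driver finds the solution near
  the baseline state selected by the secondary constraint, not a global
  optimum.
* The in-vitro rheology laws ignore the endothelial surface layer; the
  phase-separation law is applied network-wide without a threshold
  diameter.
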