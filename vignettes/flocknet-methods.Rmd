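---
title: "Models and methods: collective motion on fixed interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: collective motion on fixed interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocknet)
```

## Overview

`flocknet` studies how the *structure* of a fixed interaction network shapes
self-organized collective motion. Two archetypal models of self-propelled
agents are implemented:

* the **Vicsek-Network (VN) model**, a velocity-based model in which each
  agent repeatedly replaces its heading by the average heading of a fixed
  set of neighbours — a distributed consensus process on the network; and
* the **Active-Elastic (AE) model**, a position-based model in which agents
  are coupled by linear springs and never exchange headings; alignment
  emerges because elastic forces channel the self-propulsion energy into
  the lowest-energy collective modes.

Both models run on interaction networks that interpolate, at constant node
count $N$ and link count $K$, between a nearest-neighbour (NN) lattice and a
random network with either a Poissonian (Erdős–Rényi, ER) or a power-law
(scale-free, SF) degree distribution. The package provides the network
generators, the dynamics, the polarization order parameter, and two
estimators of the critical noise $\eta_c$ at which order is lost.

## The two models

### Vicsek-Network

The state is the vector of heading angles $\theta_i(t)$. One synchronous
update is

$$\theta_i(t+1) \;=\; \operatorname{Angle}\Big[\sum_{j \in \{i\}\cup S_i}
\hat n_j(t)\Big] + \eta\,\xi_i(t),$$

where $\hat n_j = (\cos\theta_j, \sin\theta_j)$, $S_i$ is the fixed
neighbour set of agent $i$, $\xi_i \sim U(-\tfrac12,\tfrac12)$ independently
per agent and step, and $\eta \in [0, 2\pi]$ is the noise intensity
($\eta = 2\pi$ makes each new heading fully random). Two conventions the
update needs but the defining formula does not fix:

* **Self-inclusion.** The sum includes the focal agent's own unit vector,
  matching the classic formulation of the rule as an average over the
  neighbourhood *including itself*. An isolated node therefore keeps its
  heading, plus noise.
* **Cancelling neighbourhoods.** If the vector sum vanishes exactly (a
  measure-zero event), the previous heading is kept and noise still
  applied. The numerical cutoff is $|\Sigma_x|,|\Sigma_y| < 10^{-14}$.

Positions play no role: the network is fixed, so they would only matter for
defining who interacts, which is already given.

### Active-Elastic

Each agent has a position $x_i$ and heading $\theta_i$ and obeys the
overdamped equations

$$\dot x_i = v_0\,\hat n_i + \alpha\,[F_i \cdot \hat n_i]\,\hat n_i,
\qquad
\dot\theta_i = \beta\,[F_i \cdot \hat n_i^\perp] + \eta\,\xi_i,$$

with the elastic force

$$F_i = \kappa \sum_{j \in S_i} \big(\lVert r_{ij}\rVert - l_{ij}\big)
\frac{r_{ij}}{\lVert r_{ij}\rVert}, \qquad r_{ij} = x_j - x_i.$$

Numerical conventions:

* $\hat n^\perp$ is the $+90^\circ$ (counter-clockwise) rotation of
  $\hat n$, so the torque term turns an agent *toward* the net force; the
  opposite choice is anti-restoring, which the two-agent relaxation test
  would catch immediately.
* Integration is plain forward Euler with step $\Delta t$:
  $\theta \leftarrow \theta + \Delta t(\beta F\!\cdot\!\hat n^\perp +
  \eta\xi)$. The noise term is **not** given a $\sqrt{\Delta t}$ scaling;
  $\eta$ values are therefore tied to the chosen $\Delta t$ and should not
  be compared across time steps.
* The spring constant $\kappa$ is the same for every link regardless of its
  rest length, so short- and long-range links carry equal interaction
  strength.
* Rest lengths are set to the inter-agent distances at $t = 0$
  (`assign_rest_lengths()`), so the initial configuration is stress-free:
  every elastic force at $t=0$ is exactly zero, and all later stress is
  produced by the dynamics itself.
* Coincident linked agents (undefined force direction) contribute zero
  force for that step; occurrences are counted. Positions are unbounded
  (open boundary).

Default parameters are $\alpha = 0.01$, $\beta = 0.12$, $v_0 = 0.002$,
$\kappa = 5$, $\Delta t = 0.1$ — a combination known to self-organize
rapidly and reliably on NN lattices, and kept fixed across all topologies
so only the network varies.

Noise magnitudes are **not comparable between the two models**: in VN,
$\eta$ multiplies a per-step angular kick; in AE it is a rate in a
differential equation.

## Interaction networks

All generators hold $N$ and $K$ fixed so that topologies are compared at
equal connection budget (equal mean degree $2K/N$).

**NN lattice.** Agents sit on an $L \times L$ unit-spacing grid, each
linked to its Moore neighbourhood (horizontal, vertical and diagonal first
neighbours; no wrapping). Corners have degree 3, sides 5, bulk 8, and
$K = 2(L-1)(2L-1)$ exactly.

**ER.** Uniformly random distinct pairs are linked until exactly $K$ edges
exist; the draw restarts until the graph is connected. Degrees are
Poissonian with mean $2K/N$; at the sizes used here the fraction of nodes
with fewer than two links is far below 1%, so no minimum-degree floor is
needed.

**SF.** The degree histogram is a truncated, integer-rounded power law
$n_k = \mathrm{Round}(C k^{b})$, floored at $n_k = 1$, over
$k \in [k_{\min}, k_{\max}]$ with $k_{\min} = 2$: one spring leaves an
agent free to swing about its anchor, so degree-1 nodes can never be forced
into alignment in the AE model. The pair $(C, k_{\max})$ is chosen to
minimize

$$J = W_N\,(N_{\mathrm{opt}} - N)^2 + W_K\,(K_{\mathrm{opt}} - 2K)^2,
\qquad W_N = 10,\; W_K = 1,$$

where $N_{\mathrm{opt}} = \sum_k n_k$ and $K_{\mathrm{opt}} = \sum_k k\,n_k$
is the *stub* (degree) total. Note the target for the stub total is $2K$:
each undirected link consumes two stubs, so realized networks match the NN
lattice's $K$ exactly. Because rounding makes $J$ piecewise constant in
$C$, the inner search is a deterministic two-stage grid refinement around
$C_0 = N / \sum_k k^b$; $k_{\max}$ is scanned exhaustively (the scan can
stop once even the all-ones histogram overshoots the stub target, since
both totals then only grow), and ties prefer the smaller $k_{\max}$.
Rounding is half-away-from-zero.

Integer rounding rarely hits both totals exactly, so a deterministic
adjustment follows: first the flat $n_k = 1$ tail is extended or trimmed at
the top until $\sum n_k = N$; then single nodes at the largest occupied
degree are moved one degree up or down until $\sum k\,n_k = 2K$. Every step
is logged in the result's `adjustments` attribute. This automates the small
manual corrections such constrained discrete fits otherwise need, and keeps
the result reproducible.

The histogram is then realized as a graph by stub matching, processing
nodes from the highest degree down; partners are drawn with probability
proportional to their remaining stubs. Dead ends and disconnected outcomes
restart the pass (capped at 100, then an explicit error). The realized
histogram equals the solved one exactly — this is asserted, not assumed.

**Superposition.** For $p \in (0,1)$, `superpose()` deletes
$\mathrm{round}(pK)$ random links from the NN lattice and the complementary
number from the random network, merges the remainders, collapses links
present in both, and refills the deficit with uniformly random absent edges
until exactly $K$ links remain (the refill count is recorded). $p = 0$ and
$p = 1$ return the respective edge sets unchanged. Connectivity is enforced
by redrawing, again capped at 100 attempts.

## Order parameter and critical noise

The degree of order is the polarization
$\psi = \tfrac1N \lVert \sum_i \hat n_i \rVert \in [0,1]$. All runs start
fully aligned ($\psi = 1$): for VN the stationary state is unique anyway,
while for AE the transition is discontinuous with a bistable region, and
the aligned start tracks the *ordered branch*, which is the object of
interest here. Stationary statistics discard the first half of each series
(burn-in fraction 0.5, configurable).

Two estimators of the critical noise:

* **Variance peak (VN).** At each $\eta$, the variance of $\psi$ is pooled
  over all post-burn-in samples of all runs (capturing within- and
  between-run fluctuations; the alternative — variance of per-run means —
  is available via the recorded per-run statistics). $\eta_c$ is the vertex
  abscissa of the parabola through the maximum-variance grid point and its
  two neighbours. A peak at the grid boundary or a flat profile is an
  error, never silently extrapolated.
* **Branch loss (AE).** A grid cell is *ordered* when its mean stationary
  $\psi \ge 0.5$ (configurable; the ordered branch sits well above 0.5 and
  the disordered state well below at the sizes used). $\eta_c$ is the
  midpoint between the highest ordered $\eta$ and the next tested value.
  Missing brackets (all ordered / all disordered) are errors.

Every run in a sweep draws a **fresh** network realization (and a fresh
superposition), so topology randomness is averaged over, not frozen in.

## Randomness and reproducibility

Every stochastic component takes a seed. A sweep derives one child seed per
(cell, run) with a deterministic integer hash (`derive_seed()`), and within
each run separate streams drive network generation and dynamics, so
changing one cannot shift the other. The compiled simulation cores draw
their noise from R's RNG, which makes the single-step R reference
implementations and the compiled loops consume the identical stream — the
test suite checks that a chain of R steps reproduces the compiled
trajectory. Rerunning any experiment with the same config and seed rewrites
byte-identical CSV artifacts.

## Problem sizes and what the tests show

The package ships presets at three scales. The `full` scale is the
full protocol (a $100\times100$ lattice; 8 runs of $5\times10^5$ VN steps
or 40 runs of $10^6$ AE Euler steps per noise value) and costs CPU-days;
it exists behind an explicit opt-in. The `small` scale (L = 32, 10 runs,
$2\times10^4$ VN / $10^5$ AE steps) is a desk scale for exploratory work.
The `test` scale,
used by the test suite's trend checks, reduces further to keep a full run
of the suite in minutes: L = 32, short noise grids concentrated around the
transitions, 1–4 runs per cell, $2$–$4\times10^3$ VN steps and $10^5$ AE
Euler steps, with critical-noise estimates averaged over 5 independent
estimator repetitions.

Two consequences of the reduced scale are worth stating plainly. First,
$\eta_c$ values at test scale are *smaller* than at full protocol scale:
with fewer steps the ordered branch has less opportunity to escape near the
transition for VN, and for AE a shorter horizon classifies marginal,
slowly-decaying runs as ordered or disordered differently than a
$10^6$-step run would. The package's quantitative claims are therefore
*trends across topologies at fixed protocol*, not absolute critical-noise
values. Second, trend contrasts that the full protocol resolves clearly —
notably the initial *rise* of the AE scale-free curve between $p = 0$ and
intermediate $p$, which precedes its drop toward $p = 1$ — sit near the
resolution limit of the scaled-down estimator, whereas the drop itself and
both ER trends are robust at test scale.

The synthetic lattice/ER/SF instances the tests run on emulate the study
conditions exactly (they *are* the study conditions — there is no external
data in this problem). What passing tests do **not** show is behaviour on
real animal-group interaction networks, which are neither lattices nor ER
nor degree-sequence-constrained SF graphs; the package's claims about real
systems end at the model family.

## Design choices made where the design was open

* **Stub-total constraint.** The SF constraint set is stated over node and
  link totals; with the degree histogram as the optimization variable, the
  link constraint is imposed on the stub total as $\sum_k k n_k = 2K$
  (handshake lemma), which is the only reading consistent with the NN
  lattice's published $N = 81$, $K = 272$, degree sum 544. The mean degree
  $2K/N$ interpretation of "average connections per node" corroborates it.
* **Stub partner weighting.** Partners are drawn proportionally to
  remaining stubs rather than uniformly over candidate nodes; this is the
  natural stub-matching measure and avoids biasing early (high-degree)
  nodes toward low-degree partners.
* **Superposition overlap.** Retained lattice and retained random links can
  coincide; collapsing them would silently shrink $K$, so the deficit is
  refilled with uniformly random absent links. The alternative — rejecting
  overlapping draws — distorts the retained-set distribution and can stall
  at high overlap.
* **AE ordered threshold 0.5.** Any value between the ordered branch
  (≈ 0.8–0.9 at test scale) and the disordered floor (≈ 0.03) identifies
  the same bracket in clean cases; 0.5 is the midpoint convention and is
  configurable.
* **Retry caps.** All connectivity retries are capped (default 100) and
  exhaustion is an explicit error carrying the attempt count. At
  $N = 10^4$, ER graphs at this mean degree are connected only a few
  percent of the time, so bulk ER generation at that size passes a larger
  cap explicitly rather than weakening the default.

## Known limitations

* The AE bistable region's *disordered* branch (which can extend to
  $\eta = 0$ for partly random topologies) is not mapped; all sweeps track
  the ordered branch from the aligned start.
* The Watts–Strogatz rewiring interpolation is not implemented; the
  superposition protocol is the only lattice-to-random path.
* Directed interaction networks and distance-dependent spring constants are
  out of scope.
* The VN noise convention (`eta * xi` with `xi ~ U(-1/2, 1/2)`) and the AE
  Euler noise discretization make $\eta$ values protocol-specific;
  cross-model or cross-$\Delta t$ comparisons of $\eta_c$ are not
  meaningful.

## A worked example

```{r example, eval = FALSE}
library(flocknet)

# the three topologies at the 9 x 9 budget: N = 81, K = 272
lat <- build_nn_lattice(9)
er  <- build_er(81, 272, seed = 1)
sf  <- build_sf(81, 272, b = -2, seed = 1)
degree_histogram(lat$network)  # {3: 4, 5: 28, 8: 49}
degree_histogram(er)           # Poisson-like around 2K/N = 6.7
degree_histogram(sf)           # power-law-ish, min degree 2

# a VN noise sweep on the lattice and its critical noise
sw <- bifurcation_sweep("vn", L = 16, family = "nn2er", p = 0,
                        eta = seq(0.5, 4.5, by = 0.5),
                        runs = 8, steps = 4000, seed = 7)
eta_c_from_sweep(sw)
```
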