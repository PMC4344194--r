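---
title: "Random reaction networks under thermodynamic boundary conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random reaction networks under thermodynamic boundary conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrnsim)
```

## The model

rrnsim studies how thermodynamic disequilibrium is processed by large
chemical reaction networks whose wiring is random but follows the
signatures of complex-network models. A network consists of `N` species and
reversible reactions of two kinds: *linear* reactions `X <=> Y` and
*nonlinear* (second-order) reactions `X + Z <=> Y + W`. The species-only
projection is the **substrate graph**: an edge joins two species that
appear on opposite sides of some reaction, so a linear reaction contributes
one edge and a nonlinear reaction its four reactant-product cross pairs.

With stoichiometric matrices `L` and `R` (`N = R - L`) and mass-action
one-way rates

$$v^+_j = k^+_j \prod_i x_i^{L_{ij}}, \qquad
  v^-_j = k^-_j \prod_i x_i^{R_{ij}},$$

the concentration dynamics are `dx/dt = N (v^+ - v^-)`. The environment
drives the system by clamping two **boundary species** `b1`, `b2` at fixed
concentrations `c1`, `c2`; every other species relaxes freely. All
quantities are dimensionless with `k_B T = 1`.

### Network construction

Four directed multigraph generators (self-loops and parallel edges
allowed, always exactly `M` edges, orientation uniform per edge) seed the
reaction networks:

* **ER** — both endpoints of every edge uniform over the nodes.
* **BA** — preferential attachment with `m = round(M/N)` edges per
  entering node; the entering node participates in the attachment pool at
  initial weight 1, so self-loops can occur; a path over the first `m`
  nodes seeds the process, and preferential extra edges top the count up
  to exactly `M`.
* **WS** — a ring lattice of degree `k = 2M/N` with a fraction `alpha` of
  edges rewired by re-sampling one endpoint uniformly.
* **PS** — a hierarchically modular graph: nodes sit in `2^h` elementary
  modules merged pairwise into a binary tree; an unordered node pair with
  lowest common tree level `l` is drawn with weight `p^l` (self-pairs have
  `l = 0`, which is what makes PS networks self-loop rich).

Linear networks translate each edge into one reaction. Nonlinear networks
start from `M` linear reactions and couple `C` disjoint pairs:
`A <=> B` and `C <=> D` merge into `A + C <=> B + D`, adding the substrate
edges `A-D` and `C-B`. The coupling distribution preserves the generating
model's edge statistics: uniform for ER; proportional to the product of
the products' current substrate degrees for BA; restricted to couplings
whose two new edges stay within ring distance `k/2` for WS; weighted
`p^{l_1} p^{l_2}` for PS. Consumed reactions never couple twice, and
reactions sharing a species may couple, which produces substrate
self-edges (`A + B <=> B + C`).

### Thermodynamics

Species receive Gibbs formation energies `mu0 ~ N(0, 1)`. Each reaction
samples one activation energy from the Planck-like density

$$P(x) = \frac{6}{\pi^2} \frac{1}{x^3\,(e^{1/x} - 1)},$$

which has an effective lower bound near `x ~ 0.2` and a `x^{-2}` tail
(infinite mean — some reactions are effectively frozen because
`k = e^{-E_a}` underflows; the analysis handles them in log space). The
sampled barrier is assigned to the exergonic direction and the opposite
direction receives `E_a + |\Delta\mu_0|`, so `k^+/k^- = e^{-\Delta\mu_0}`
and every closed network satisfies detailed balance with Boltzmann
stationary state `x_i \propto e^{-\mu_{0,i}}`. (The alternative reading in
which the sampled barrier sits on the endergonic direction is available as
`direction_rule = "literal_text"`; it breaks equilibrium balance and is
excluded from all validation.) Before a clamped run the two boundary
species' `mu0` are set to zero and all energetics recomputed
(`rezero_boundary()`), which removes the formation-energy offset from the
boundary driving force and makes the balance identity below exact.

At steady state the per-reaction entropy production rate is

$$\sigma_j = (v^+_j - v^-_j)\,\ln\frac{v^+_j}{v^-_j} \ge 0,$$

identically equal to `-(\sum_m \mu_m N_{mj}) v_j` with chemical potentials
`\mu_i = \mu_{0,i} + \ln x_i` (the package computes both routes and tests
their agreement; the stoichiometric form is stated with the sign that
makes spontaneous flow dissipate positively). Summed over reactions and
with re-zeroed boundary energies, the whole network acts like one
imaginary linear reaction between the boundary species:

$$\sigma_{tot} = v \,\ln\frac{c_1}{c_2},$$

where `v` is the net boundary conversion flow. This identity is the
package's principal internal consistency check; converged runs satisfy it
to a relative residual far below `1e-4`.

## Steady-state computation

The reference integrator is an adaptive Dormand-Prince 5(4) scheme
(compiled; positivity enforced by step rejection, no epsilon floor).
Integration stops at `t = 50000` or when the mean squared concentration
change per species and step length drops below `1e-20`. Hitting `t_max`
is not an error: the state is flagged and its final rates used, because
networks with deeply frozen reactions relax on timescales beyond any
horizon.

Because the explicit scheme resolves the fastest reaction while the
interesting relaxation is much slower, `accelerate = "auto"` adds two
exact shortcuts, both validated against plain integration in the test
suite:

* purely linear clamped networks solve their (sparse, grounded-Laplacian)
  linear steady state directly; substrate components not containing a
  boundary species take their closed-form Boltzmann equilibrium at the
  component's initial mass;
* nonlinear networks integrate in growing chunks and attempt a damped
  Newton iteration (analytic sparse Jacobian) once transients have mostly
  relaxed; conservation rows replace the stationarity equations of
  components that contain no boundary species, and species whose incident
  reactions are all kinetically frozen are pinned, which keeps the
  Jacobian nonsingular.

A stiff-capable multistep route (`method = "lsoda"`) serves as an
independent cross-check; the three routes agree on steady flows to at
least six digits on the validation networks.

## Measured quantities and conventions

* **Topology census.** Mean shortest path is measured on the *directed*
  simplified substrate graph over reachable ordered pairs, and the
  clustering coefficient is the *global* transitivity of the simple
  undirected projection; modularity is Newman modularity of the walktrap
  partition (4-step walks) on that projection. These conventions were
  fixed by validating all four linear ensembles against their published
  reference statistics; the undirected path length and the average local
  clustering remain available (`clustering = "local"`, undirected input).
* **Cycle census.** 1-cycles are self-loop edge instances; 2-cycles are
  unordered pairs of antiparallel edge instances between distinct nodes;
  4-cycles are simple directed cycles over four distinct nodes counted
  once per rotation class, computed from closed-walk counts corrected for
  node repetitions and cross-checked against a brute-force enumerator.
  Cycle *excess* compares the flow-directed substrate graph against the
  mean of 10 random per-reaction reorientations of the same network.
* **Dissipation distribution.** Pooled `sigma` samples are log-binned and
  the density slope is fitted by least squares inside a quantile window.
  `sigma` spans tens of decades, so the power-law ("intermediate") region
  sits in the upper quantiles: the default window `[0.70, 0.999]`
  corresponds to the stretch where the complementary cumulative
  distribution falls from roughly 0.3 to 1e-3, which is the straight
  region of the cumulative plot. The window is configurable and always
  recorded in the fit object; a Pareto maximum-likelihood variant is
  provided for sensitivity analysis.
* **Flow sign.** `boundary_flow` is positive for net conversion from `b1`
  to `b2`; ensemble tables additionally report the flow in the direction
  of the concentration drop, which is the positively plotted quantity.

## Synthetic-data scope and default parameters

The generator defaults are the study conditions: `N = 1000` species,
`M = 5000` linear reactions (or `M = 3000` with `C = 1000` couplings for
nonlinear networks), `alpha = 0.1`, `p = 0.5`, `h = 8`, boundary
concentrations `c1 = 0.1` and `c2 = 1` (or a ladder `c2 = 0.2 ... 60`),
50 boundary pairs per shortest-path distance and 10 network replicates.
These artificial ensembles deliberately ignore element balance and atom
mapping: any species pair may interconvert, which guarantees many
transformation pathways between random boundary pairs. Passing tests on
them says nothing about networks with conservation constraints
(real chemistries concentrate cycles and clustering far beyond these
nulls), about reaction orders above two, or about stochastic (small copy
number) kinetics.

Desk-scale replication in the test-suite and acceptance runs uses reduced
ensembles chosen as a compromise between statistical stability and
turnaround: 10 network samples for the census; 2 networks per model and
10 boundary pairs at distance 4 for the dissipation distribution; one
disequilibrium ladder on the ER ensemble with 4 rungs (`c2` up to 30) and
5 pairs at distance 3; distance scans with 2 networks and 5 pairs per
distance; 25-seed edge-count sweeps at `N = 120`. These sizes are stated
once here and are not tuned per run.

## Known limitations

* The nonlinear coupling stage reproduces the reaction-count arithmetic
  and substrate edge budget exactly, but several published small-cycle and
  clustering statistics of *nonlinear* ensembles cannot be derived from
  the stated construction (a coupled reaction's four cross pairs are
  pairwise distinct, so no orientation convention yields intra-reaction
  2-cycles); the package reports what the documented construction
  produces.
* Newton acceleration returns *a* stationary point of the clamped
  kinetics. Mass-action systems with couplings can in principle be
  multistable; route-agreement tests cover the ensembles used here, but
  pathological cases should be run with `accelerate = "none"`.
* Non-converged runs (flagged `converged = FALSE`) are retained in
  ensemble tables, mirroring the use of final rates as steady-state rates;
  their balance residuals are the honest diagnostic.
* The degree-resolved dissipation profile is a pooled mean and is
  dominated, at desk-scale replication, by rare low-degree bottleneck
  species that carry the whole boundary flux; comparisons between linear
  and nonlinear profiles stabilize only at full replication (tens of
  networks, 50 pairs per distance).
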