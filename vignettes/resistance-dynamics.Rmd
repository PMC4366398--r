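---
title: "Modelling drug-resistance evolution across spatial compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug-resistance evolution across spatial compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialresist)
```

## The model

`spatialresist` models a population of cancer (or microbial) cells spread
over `M` spatial compartments that differ in drug concentration — distal
metastatic lesions, poorly vascularised tumor regions, pharmacological
sanctuaries.  A cell is characterised by its genotype `i` (the number of
resistance point mutations it carries, `0 .. n-1`) and its compartment `j`.
Cells divide, die, mutate and migrate independently (a multi-type
branching process; no density regulation), with rates per cell per day:

* **Division** at rate `b_ij`, given by a Hill dose-response landscape

  $$b_{ij} = \frac{\beta_j\,(1 - i\,s)}{1 + \left(D_j / (\rho^i\,
  \mathrm{IC}_{50})\right)^m},$$

  where `beta_j` is the compartment's drug-free division rate, `D_j` its
  drug concentration, `s` the fitness cost per mutation in the absence of
  drug, `rho >= 1` the fold-increase in IC50 per mutation and `m` the Hill
  steepness.  Each mutation both costs (factor `1 - i s`) and protects
  (IC50 scaled by `rho^i`).
* **Mutation**: at division, one daughter carries one additional mutation
  with probability `u`; mutation is strictly stepwise and irreversible,
  and the top genotype mutates no further.
* **Death** at rate `d_ij = alpha_j`: drug action is cytostatic
  (inhibits division), not cytotoxic, so death rates are drug- and
  genotype-independent within a compartment.
* **Migration**: a cell changes compartment (keeping its genotype) at
  total rate `v`, split across targets by the topology — `pairwise`
  (two compartments), `ring` (both nearest neighbours at `v/2`), `global`
  (each other compartment at `v/(M-1)`), or `line` (a radial sequence of
  shells).

A compartment where sensitive cells remain supercritical
(`b_0j > alpha_j`) because little drug reaches it is a *sanctuary*; it can
rescue the treatment-failure pathway even when every other compartment
would eradicate sensitive cells.

## Lineage generating functions

All probabilistic output flows from the per-lineage probability generating
functions `F_ij(X; t) = E[prod_kl x_kl^(N_kl(t))]` for the lineage founded
by a single `ij` cell, which satisfy the backward Kolmogorov system

$$\partial_t F_{ij} = d_{ij} + b_{ij}(1-u)F_{ij}^2
  + b_{ij}\,u\,F_{ij}F_{(i+1)j} + \sum_k v_{j\to k} F_{ik}
  - (d_{ij} + b_{ij} + v)\,F_{ij}, \qquad F_{ij}(X;0) = x_{ij}.$$

`pgf_rhs()` evaluates this vector field for any model assembled by
`branching_model()` or `build_pathway()`; `solve_pgf()` integrates it with
a stiff-capable adaptive solver (`deSolve::lsoda` for real evaluation
points, `deSolve::zvode` for complex ones).

**Deficit coordinates.** The quantities of interest are often `1 - F` at
the level of `u` (1e-9) or `u*v`; forming them by subtraction after
integrating `F` itself would lose them to rounding.  Real points in
`[0,1]` are therefore integrated in deficit coordinates `G = 1 - F`,
whose equations follow by substitution and contain no cancelling
constants.  Relative tolerance `1e-10` and absolute tolerance `1e-20` on
`G` keep errors far below `1/N` for censuses up to `1e11` cells.

**The `t -> Inf` limit** (extinction/no-escape probabilities) is the
fixed point the backward flow reaches from the evaluation point.
`limiting_pgf()` integrates in doubling time chunks and accepts the limit
only when a damped Newton iteration on the algebraic fixed-point system
converges from the current state (locality-bounded steps, so it cannot
jump to a different root of the quadratic system).  This is deliberate:
with a near-critical sanctuary, the deficit of the sensitive class is
seeded at order `u` by the mutation term and grows on the timescale
`1/(b - d)` — thousands of days — before saturating.  A residual
threshold alone would accept a spurious early plateau; a failed Newton
polish instead sends the driver back to integrate further.

## Escape probability and relapse times

Setting the dummy variables of a chosen resistant set to 0 and all others
to 1 (`resistant_mask()`, default: top genotype in any compartment) makes
`F(X_m; t)` the probability that a lineage holds no resistant cells at
time `t`, and `F(X_m; Inf)` the probability that it never establishes a
surviving resistant population.  Lineages are independent, so an initial
census `N_ij` composes multiplicatively:

$$P(\text{escape}) = 1 - \prod_{ij} F_{ij}(X_m;\infty)^{N_{ij}},$$

evaluated in the log domain (`log1p`/`expm1` on the deficits), since
`(1-\epsilon)^{10^{11}}` underflows naively.  The conditional
no-resistance curve and the mean relapse time are

$$p_s(t) = \frac{\prod F^{N}(t) - \prod F^{N}(\infty)}
  {1 - \prod F^{N}(\infty)},\qquad
  \bar T_r = \int_0^\infty p_s(\tau)\,d\tau,$$

computed by trapezoid quadrature on an adaptive grid that doubles its
horizon until `p_s` is provably small — the criterion uses the distance
between the current state and the known fixed point to bound all future
`|p_s|` — plus an exponential tail fitted to the final decade of decay.

**Where the conditional time is meaningful.**  `p_s(t)` conditions on
*eventual* resistance (`F(X_m; Inf)` counts lineages with resistant cells
surviving at `t = Inf`).  In regimes where every compartment is
subcritical for sensitive cells and escape is rare, resistant clones that
appear transiently and die out make `P(no resistance at t)` dip *below*
its `t -> Inf` limit before recovering — the test suite demonstrates the
dip and its recovery against the exact stochastic simulator — so `p_s`
takes negative values and its integral is not a mean waiting time there.
The formula is reported as defined; interpret `mean_time` only where the
escape probability is appreciable (it is the standard object on the
treatment-failure side of the sharp transition).  This is also why the
mean relapse time is not monotone across the full sanctuary transition in
the two-lesion concentration-difference sweep: it is small below the
transition (rare, early, short-lived conditioning events), diverges as
the sanctuary crosses criticality, and only then decreases with
increasing heterogeneity.

## Joint count distributions by PGF inversion

The joint law of the resistant counts in two chosen classes follows from
the PGF by Cauchy's integral formula, discretised by the trapezoid rule on
the unit torus — equivalently an `N x N` two-dimensional DFT of
`F(e^{i\theta_1}, e^{i\theta_2}; t)` with the remaining coordinates
clamped at 1.  `joint_count_distribution()` integrates all `N^2` initial
conditions as one stacked complex ODE system (only the initial conditions
differ), then applies `fft()`.  Numerical safeguards, in order: the
full-grid mass must equal 1 to `1e-6` (the DFT identity makes this a pure
integrator check), negative entries beyond `-1e-8` are an error, and only
then is residual noise clipped; mass in the outer half of the grid
triggers an aliasing warning, since counts beyond `N` fold back onto the
grid.  The default `grid_size = 128` resolves counts up to 20 with room
to spare (the reference setting `N = 1000` is supported but unnecessary:
window probabilities change by less than `1e-6` between grids of 128 and
256 at the panel parameters).

## Competing pathways to resistance

With a sanctuary (compartment 0) and a drug compartment (1), resistance
in the drug compartment can arrive by two routes: *migration-mutation*
(sensitive cells migrate first, mutate in situ) and *mutation-migration*
(mutate in the sanctuary first, then migrate).  `build_pathway()`
realises each as its own three-class chain with strictly one-directional
transitions — bespoke models rather than the full model with rates
zeroed, because bidirectional migration would mix the pathways.  In the
low-rate limit the mutation-migration pathway is faster iff

$$\frac{b_{00}}{(b_{00}-d_{00}) - (b_{10}-d_{10})} >
  \frac{b_{01}}{(b_{00}-d_{00}) - (b_{01}-d_{01})},$$

which under equal death rates reduces to `delta > s/(1+s)` with
`s = 1 - b10/b00` and `delta = 1 - b01/b00`
(`pathway_dominance_general()`, `pathway_dominance_simplified()`; the two
predicates agree exactly under the equal-death parameterisation, a
property the test suite checks on 2000 random landscapes).  A neutral or
advantageous mutation (`s <= 0`) makes the left side diverge:
mutation-migration always wins.  `pathway_crossing_delta()` locates the
crossing of the two conditional mean-time curves by bisection (absolute
tolerance `1e-4` in `delta`); at low rates it recovers the analytic
threshold.  The sanctuary-rescaling factor `phi` multiplies all four
sanctuary rates (`scale_sanctuary()`); note that the two natural
parameterisations of this rescaling coincide once `b00` itself is scaled,
so only one is implemented.

Landscape validation is deliberately permissive: only sanctuary
supercriticality (`b00 > d00`) and a viable resistant class under drug
(`b11 > d11`) are hard errors, because drug-efficacy scans legitimately
cross the remaining canonical inequalities (`b01 < d01` fails for small
`delta`); those deviations warn only on request.

## Scenario builders

* `build_two_lesion()` — two metastatic lesions under a fixed total drug
  budget, concentrations `D0 = Dbar - dd/2`, `D1 = Dbar + dd/2`.
  Defaults: `N0 = 1e3` slow-growing poorly-penetrated cells
  (`beta = 0.05`, `alpha = 0.04`) and `N1 = 1e8` fast-growing well-drugged
  cells (`beta = 0.5`, `alpha = 0.4`), `IC50 = 50`, `m = 2`, `rho = 5`,
  `s = 0.01`, `u = 1e-9`.
* `build_onion()` — a solid tumor (default `1e11` cells, 4.6 cm diameter)
  as `M = 30` concentric shells of equal width around a central vessel;
  proliferation, turnover, cell density and drug all decay exponentially
  with distance (`tau_g`, `tau_c`, `tau_D`).  Shell rates are evaluated at
  midpoints (compartments are homogeneous by construction, and refining
  `M` changes little); populations integrate the density over the shell
  with a spherical `x^2` volume element by default (`cylindrical` uses
  `x`; the section-view geometry does not fix the dimensionality, and
  spherical matches the stated cell count/diameter pair), rounded by
  largest remainder so the total is exact.  Radial migration uses the
  `line` topology; the published rule gives `v/2` per neighbour, which
  leaves total outflow `v/2` at the two edge shells — preserving the
  stated per-neighbour rate verbatim — with `edge_rule = "full"` exposing
  the alternative reading.
* `build_ring()` — `M` compartments on a ring (or fully connected) with a
  Gaussian concentration bump centred on the middle compartment, rescaled
  to mean `Dbar`.  The heterogeneity parameter `sigma` is the *standard
  deviation of the concentration values across compartments* (so larger
  `sigma` means more heterogeneity, up to the single-compartment spike at
  `Dbar * sqrt(M-1)`); the bump width realising it is found by root
  solving.  The founder census defaults to one sensitive cell in the
  lowest-concentration compartment.

`scenario_sweep()` maps any of these over a parameter grid and returns a
tidy table of escape probabilities or mean times.

## The stochastic oracle

`simulate_branching()` is an exact direct-method SSA of the identical
process, written in C++: exponential waiting times at the total rate,
event selection proportional to rates, one daughter mutating with
probability `u` at division.  Tau-leaping is deliberately absent — the
simulator's purpose is exactness (large populations are the PGF engine's
job).  Replicates draw from counter-derived xoshiro256++ streams
(`seed` x replicate index), so ensembles are reproducible and
order-independent; supercritical escapees are stopped at a configurable
population cap (default `1e6`) and flagged.  The test suite uses it to
validate extinction probabilities, masked-PGF curves (including the
transient dip), the inverted joint distribution (total-variation
distance), and the conditional mean-time functional on a scaled-down
two-lesion scenario.

## Numerical choices and problem sizes

* Integrator tolerances: `rtol = 1e-9 / atol = 1e-12` for complex torus
  batches; `rtol = 1e-10 / atol = 1e-20` in deficit coordinates.
* Mean-time quadrature: 200 grid points per doubling chunk, stop at
  `p_s < 1e-5` with a fixed-point-gap bound on the tail, exponential tail
  correction.
* Bisection for the pathway crossing: `delta` tolerance `1e-4`.
* Test-suite simulation sizes: `1e4` replicates for probability checks
  (Monte-Carlo SE about 0.003), `1e5` for the joint histogram, 100
  ensembles of 400 for interval coverage, 1500-3000 for curve-level
  comparisons on scaled scenarios (initial censuses of `~1e3` cells and
  mutation rates raised to keep `u x N` supply comparable); these sizes
  put 3-sigma Monte-Carlo bands well inside the effects being tested.

## What the generators do and do not emulate

The scenario builders reproduce the study conditions exactly as printed
(rates, censuses, dose-response parameters).  They share the branching
assumptions: no carrying capacity or cell-cell competition, no
quiescence, no death-rate drug action, memoryless migration between
homogeneous compartments, and deterministic drug fields constant in time.
Passing tests therefore validate the mathematics of the compartment
branching model, not pharmacokinetics or spatially continuous tumors;
conclusions transfer to real systems only insofar as those assumptions
do.  Back-mutation, multi-drug epistasis and genotype-dependent motility
are out of scope.
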