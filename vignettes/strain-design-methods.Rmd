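---
title: "Kinetic-ensemble strain design: models, screens and the design MILP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic-ensemble strain design: models, screens and the design MILP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainkin)
```

## The problem

Given a metabolic network with known stoichiometry and regulatory
annotations, which enzyme activities should be changed -- and by how much --
to raise the yield of a product on its substrate, without wrecking the
organism's physiology? Kinetic models can answer this, but their parameters
are mostly unknown. strainkin follows the ensemble strategy: build *many*
kinetic models that all reproduce the observed steady state, keep the ones
whose dynamics look like the real strain, and then design interventions that
work across the surviving population rather than for any single parameter
guess.

The workflow has three stages.

1. **Thermodynamically consistent steady states.** Flux balance is augmented
   with Gibbs-energy variables: for every constrained reaction,
   $\Delta G' = \Delta G'^0 + RT \sum_i n_i \ln x_i$, and a big-M binary per
   reaction couples the flux sign to $\mathrm{sign}(\Delta G') < 0$ (second
   law). Steady-state samples at a minimum fraction of maximal growth
   (default 0.8) are drawn by optimizing random objective directions over
   the flux and log-concentration variables and recording the vertex. This
   sampler is simple and bit-reproducible under a seed; a hit-and-run
   refinement would cover the interior but is unnecessary for ensembles
   anchored at extreme phenotypes.

2. **Kinetic models anchored to each steady state.** Every reaction gets a
   mechanism by stoichiometry class: generalized reversible Hill
   (Hofmeyr/Cornish-Bowden form, Hill coefficient $h = 1$ by default) for
   one-substrate/one-product enzymes, convenience kinetics for
   multi-substrate reactions including the biomass lump, and mass action for
   exchange pseudo-reactions and boundary transports. All saturable laws
   share the skeleton
   $$v = V_{\max}\,\frac{S \cdot (1 - \Gamma)}{D}\cdot a_{\mathrm{reg}},$$
   where $S$ is the substrate occupancy product, $\Gamma =
   \exp(\Delta G'/RT)$ the thermodynamic displacement, $D$ the law-specific
   saturation denominator and $a_{\mathrm{reg}}$ the regulatory factor
   (competitive terms add to $D$, uncompetitive terms multiply it,
   activation is a hyperbolic -- optionally cooperative -- factor on the
   numerator). This skeleton makes two properties structural rather than
   numerical: the rate sign always equals the driving-force sign (zero
   exactly at equilibrium), and the Haldane relation is enforced because
   $K_{eq} = \exp(-\Delta G'^0/RT)$ enters only through $\Gamma$.
   Parameters are back-calculated from sampled saturations
   $\sigma \sim U(0.01, 0.99)$ per binding site via
   $K = x_{ss}(1-\sigma)/\sigma$, and $V_{\max}$ is solved in closed form so
   the rate reproduces the anchor flux exactly. Models whose reduced
   Jacobian has any eigenvalue with non-negative real part are discarded
   when stability pruning is on.

3. **Screening, design, and nonlinear validation.** Models are filtered by
   (i) linearized dynamics: the dominant time constant
   $\tau_d = 1/\min_i |\mathrm{Re}(\lambda_i)|$ (conserved-moiety zero
   eigenvalues removed by link-matrix reduction first) must be below one
   fifth of the doubling time, so perturbations settle to 99.3% within one
   doubling -- the generalization behind case-specific presets such as 24 or
   43 minutes; (ii) reproduction of batch fermentation curves (final
   biomass within 5%, final product within 10%, substrate exhaustion before
   20 h by default), or, absent data, recovery from k-fold concentration
   perturbations; and (iii) robustness to enzymatic noise: all $n$ trials
   with $V_{\max} \cdot (1 + N(0, cv^2))$ perturbations must keep at least
   half the reference final biomass. For each surviving model the package
   computes log-linear elasticities analytically, solves the
   control-coefficient system
   $C_x = -(N_R V E_x L_s)^{-1} N_R V \Pi$, $C_v = E_x L_s C_x + \Pi$
   (summation theorems are asserted at $10^{-8}$), and casts strain design
   as a MILP over the control coefficients: maximize
   $\Delta \ln(\text{product flux}) - \Delta \ln(\text{uptake flux})$
   subject to bounded concentration responses, a bounded growth drop, a cap
   on the number of interventions and on per-enzyme fold changes.
   Alternative designs within 5% of the optimum are enumerated with integer
   cuts on the signed support, scored across all models by their mean
   NRA objective, and the top designs are re-validated in nonlinear batch
   simulations, ranked by median titer, and stress-tested under ±50%
   expression uncertainty.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `growth_fraction` | 0.8 | -- | steady-state samples stay near-maximal growth |
| `min_displacement` | 1e-3 | kcal/mol | keeps the second law strict, not marginal |
| `RT` | 0.5925 | kcal/mol | 298.15 K; configurable |
| saturation range | (0.01, 0.99) | -- | avoids degenerate $K_m$ at the ends |
| `tau_max` | doubling/5 | h | the 99.3%-settling rule |
| fit tolerances | 5% / 10% / 20 h | -- | final biomass, final product, fermentation time |
| `cv`, `n`, `growth_floor` | 0.10, 50, 0.5 | -- | enzymatic-robustness screen |
| `conc_fold` | 3 | fold | phenotype proximity (concentrations) |
| `up_fold` / `down_fold` | 5 / 100 | fold | "unrestricted" downregulation needs a finite MILP bound; 100 is the documented stand-in |
| `max_interventions` | 3 | count | design size cap |
| `growth_drop_max` | 0.2 | -- | engineered strain keeps 80% of growth |
| enumeration `tolerance` | 0.05 | -- | near-optimal alternative designs |
| `epsilon_membership` | 1e-6 | log-fold | a set direction binary implies a real activity change; also used when a fixed membership is re-scored across models |
| `rtol` / `atol` | 1e-8 / 1e-10 | -- | stiff integration; screening depends on accurate relaxation |

A second-study preset (`up_fold = 10`, `conc_fold = 2.5`) mirrors the
common situation where one deliberately allows stronger expression changes
and compensates with a tighter metabolite envelope.

## The synthetic study system

All tests and the acceptance analysis run on generated fixtures
(`make_toy_network()`), because a reduced genome-scale model and measured
fermentation data cannot ship with the package. The flagship topology,
`feedback_branch`, is a 12-reaction, 11-metabolite, 3-compartment network:
glucose-like uptake, an ATP/ADP conserved pair, a branch point whose
product-bound entry (`BR1`) is competitively inhibited by the end product
`F` of the competing branch (the planted bottleneck, mimicking
end-product inhibition of the first committed step of an aromatic pathway),
periplasmic product export, and a biomass lump that needs both branches.
Other topologies cover a linear chain, an unregulated branched network, a
deliberately bistable self-activation loop (which must *fail* the
concentration-robustness screen), and a closed-carbon pathway with integer
carbon counts for elemental audits.

Fixture conditions were fixed once, on physiological grounds: boundary
concentrations pinned (substrate 0.02 mol/L, product initially absent) so
batch media equal anchors and substrate exhausts within the horizon;
internal concentrations in 1e-6..0.01 mol/L; every toy enzyme displaced at
least 0.1 kcal/mol from equilibrium; a minimum product-pathway flux of one
tenth of the uptake cap (the reference strain visibly secretes product);
boundary carriers mass-action and strongly displaced (PTS-like rigid
uptake). Pseudo-experiments add 5% multiplicative Gaussian noise in
triplicate. The default study size is 6 steady-state samples x 6 parameter
draws per sample; the acceptance analysis uses ensembles up to ~1000 models
where only model construction is exercised.

What passing on these fixtures does **not** show: the toys have no
cofactor-coupled branching beyond one moiety, no isoenzymes or shared
enzymes, a single lumped biomass reaction whose flux *is* the growth rate
(1/h convention), noise that is i.i.d. multiplicative rather than
structured, and 7-8 designable enzymes -- far from genome scale. Results on
real networks depend on data quality and model reduction upstream of this
package.

## Numerical and design choices

* **LP/MILP kernel.** All optimization runs on an in-package dense
  two-phase bounded-variable simplex with deterministic pivoting and a
  branch-and-bound layer. Inequality-only problems (the design MILP) start
  from a feasible slack basis and skip phase 1. Problems here have tens of
  variables; an external solver would add a dependency without changing
  results. Correctness is cross-checked in the tests against an independent
  LP implementation and brute-force enumeration.
* **Conservation analysis** uses row-reduced elimination with a 1e-9 zero
  tolerance, giving a reproducible left-null-space basis; the link matrix
  (concentration-scaled where log coordinates are involved) removes
  structural zero eigenvalues before any spectral screening.
* **Elasticities are analytic**, hand-derived per law; central finite
  differences (relative step 1e-6) serve as the independent oracle in the
  tests, never as the implementation.
* **Yield rows.** Exchange pseudo-reactions act on fixed boundary species
  and therefore carry structurally zero control; the MCA/NRA objective
  reads the product (uptake) response at the last transport feeding (first
  consuming) the boundary species, which carries the same steady-state flux.
* **Dilution term.** Batch simulations include the intracellular dilution
  term $-\mu x$ by default. The toy configuration switches it off so the
  anchored state is an exact exponential-phase steady state (growth holds at
  the anchor rate until substrate exhaustion); the closed-carbon audit runs
  with dilution on, where total carbon (medium + intracellular + biomass) is
  conserved exactly.
* **Integer cuts** exclude the exact signed support; a set direction binary
  forces at least `epsilon_membership` of log activity change, so binaries
  and active supports coincide and the enumeration terminates.
* **Degenerate inputs.** Zero anchor fluxes give zero maximal rates (the
  reaction is dead in that model); near-equilibrium reactions give large but
  finite elasticities and are listed by `near_equilibrium_report()` rather
  than erroring -- enzymes operating near equilibrium exert little flux
  control, which is also why a displacement floor (e.g. 1.25 kcal/mol) can
  be imposed on a reaction before sampling.
* **Ties** break lexicographically everywhere (target ranking, design
  ranking), making every ranking deterministic.

## Open choices made here

The Hill cooperativity of the reversible Hill law defaults to 1 (reducing
to reversible Michaelis-Menten form) with a per-reaction override, since
nothing in the mechanism assignment forces cooperativity. The
concentration-perturbation screen draws each species up or down by the full
k-fold factor (signs i.i.d.), the strictest reading of a "k-fold
perturbation". The recovery band is 1% per species, matching the
99%-recovery spirit of the settling rule. Control coefficients are computed
per model, not on a consensus linearization. Whether a 24- or 26-minute
threshold is used for a 130-minute doubling time is immaterial here: both
are presets of the same doubling/5 rule.

## Known limitations

The vertex sampler concentrates on extreme phenotypes; interior steady
states are underrepresented. The MILP is exact only for the log-linear
approximation -- nonlinear growth after an intervention lands within a few
percent of the constrained bound, which is why designs are always
re-validated by simulation. Fold-change bounds on *fluxes* are implemented
but off by default. Gene-level interventions (operons, shared subunits) and
heterologous knock-ins are out of scope.
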