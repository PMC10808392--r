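# strainkin

Rational metabolic strain design with ensembles of nonlinear kinetic
models, for metabolic engineers and systems biologists who need enzyme
targets that respect physiology rather than just maximize a flux on paper.

Because the kinetic parameters of a metabolic network are mostly unknown,
strainkin never trusts a single model. It

1. samples steady states (fluxes **v**, log-concentrations **ln x**, Gibbs
   energies ΔG′) consistent with mass balance `N v = 0`, bounds, and the
   second law — every carried flux satisfies `sign(v)·ΔG′ < 0` with
   `ΔG′ = ΔG′⁰ + RT Σᵢ nᵢ ln xᵢ` — via a mixed-integer TFA formulation, at
   ≥ 80 % of maximal growth;
2. builds, around each steady state, kinetic models whose parameters are
   back-calculated from sampled enzyme saturations
   (`Km = x_ss(1−σ)/σ`, Vmax solved so the rate law reproduces the anchor
   flux exactly, Haldane relation via `Keq = exp(−ΔG′⁰/RT)`), keeping only
   locally stable models;
3. screens the ensemble by its dominant time constant
   `τ_d = 1 / minᵢ |Re(λᵢ)|` (must beat one fifth of the doubling time, so
   responses settle to 99.3 % within one doubling), by reproduction of batch
   fermentation curves, and by robustness to random Vmax perturbations;
4. computes flux/concentration control coefficients
   (`C_x = −(N_R V E_x L)⁻¹ N_R V Π`, `C_v = E_x L C_x + Π`; summation
   theorems `Σ C_v = 1`, `Σ C_x = 0` checked at 1e−8) and solves a
   mixed-integer linear program over them — maximize
   `Δln v_product − Δln v_uptake` subject to ≤ 3-fold concentration changes,
   ≤ 20 % growth loss, ≤ 3 interventions, ≤ 5-fold upregulation — then
   enumerates all designs within 5 % of the optimum;
5. ranks the unique designs across the model ensemble and re-validates the
   best in stiff batch-bioreactor simulations, including ±50 % expression
   sensitivity analysis and Jaccard clustering of design memberships.

Everything runs on built-in toy fixtures (10–25 reactions, generated in
code), so the package is fully testable offline.

## Worked example

```r
library(strainkin)

net <- make_toy_network("feedback_branch")   # planted feedback bottleneck
net
#> Metabolic network: 12 reactions, 11 metabolites, 3 compartment(s), 1 regulatory interaction(s)
#>   biomass: BIO  product: EX_ant  uptake: UPT

gt       <- make_ground_truth_model(net, seed = 5)       # "the real strain"
profiles <- sample_steady_states(net, gt$thermo, gt$flux_bounds, n = 2, seed = 1)
models   <- sample_kinetic_models(net, gt$thermo, profiles, per_profile = 3, seed = 1)
models[[1]]
#> Kinetic model: 12 reactions | laws: convenience=2, generalized_reversible_hill=6, mass_action=4 | anchor growth 0.54

eigen_summary(models[[1]])$tau_d * 60        # dominant time constant, minutes
#> 5.6

cc <- control_coefficients(models[[1]])
cc
#> Control coefficients: 12 fluxes x 12 enzymes; 9 species
#>   top yield control: BR1, BR2, BIO

design <- solve_nra(build_nra_problem(cc, net))
design
#> Intervention design: BR1+ x2.43, HEX+ x4.97, TRA+ x1.28
#>   predicted yield gain: 77.5% (log objective 0.5738)

cfg <- make_toy_bioreactor_config(models[[1]])
simulate_batch(models[[1]], cfg)                                  # reference
#> Batch trajectory: 200 points over 20 h | final biomass 3.365 g/L | final product titer 0.9488
simulate_batch(apply_design(models[[1]], design$interventions), cfg)
#> Batch trajectory: 200 points over 20 h | final biomass 2.3 g/L | final product titer 1.479
```

The design upregulates the feedback-inhibited branch entry `BR1` (the
planted bottleneck), the committed upstream step and the product transport;
nonlinear resimulation confirms a ~56 % titer gain at a modest biomass
cost. `run_pipeline()` wraps the whole study (sampling → screening → design
→ cross-model ranking) in one call, and `exec/strainkin` exposes
`fixtures`, `pipeline`, `simulate` and `mca` subcommands for shell use.

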