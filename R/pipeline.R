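#' Run the full strain-design pipeline on a toy study
#'
#' Orchestrates the three-step workflow end to end on a generated fixture:
#' (1) sample thermodynamically consistent steady states and build a kinetic
#' model ensemble around them; (2) screen the ensemble by linearized
#' dynamics, reproduction of (pseudo-)experimental fermentation curves, and
#' robustness to enzymatic perturbations; (3) compute control coefficients
#' for the retained models, enumerate near-optimal intervention designs with
#' the network-response MILP, and rank the unique designs by their mean
#' cross-model objective.
#'
#' @param topology fixture topology (see [make_toy_network()]).
#' @param seed RNG seed; the whole run is reproducible.
#' @param n_profiles steady-state samples.
#' @param per_profile kinetic models per steady state.
#' @param noise_cv pseudo-experiment noise level.
#' @param tolerance NRA enumeration tolerance (default 5%).
#' @param conc_fold,up_fold,max_interventions,growth_drop_max design bounds.
#' @param n_enz_trials enzyme-robustness trials per model during screening.
#' @param top_k designs to rank.
#' @return list: the network, ground truth, ensemble, screening report,
#'   per-model enumerations, ranked designs, and the NRA problems.
#' @export
run_pipeline <- function(topology = "feedback_branch", seed = 1,
                         n_profiles = 6, per_profile = 6,
                         noise_cv = 0.05, tolerance = 0.05,
                         conc_fold = 3, up_fold = 5, max_interventions = 3,
                         growth_drop_max = 0.2, n_enz_trials = 5,
                         top_k = 5) {
  net <- make_toy_network(topology)
  gt <- make_ground_truth_model(net, seed = seed + 900000L)
  config <- make_toy_bioreactor_config(gt$model)
  data <- generate_pseudo_experiment(gt$model, config, noise_cv = noise_cv,
                                     seed = seed + 800000L)
  profiles <- sample_steady_states(net, gt$thermo, gt$flux_bounds,
                                   n = n_profiles, seed = seed)
  models <- suppressWarnings(
    sample_kinetic_models(net, gt$thermo, profiles,
                          per_profile = per_profile, seed = seed))
  scr <- screen_ensemble(models, data, config, n_enz = n_enz_trials,
                         seed = seed)
  retained <- models[scr$retained]
  enumerations <- list(); problems <- list(); ranked <- NULL
  if (length(retained) > 0) {
    ccs <- lapply(retained, control_coefficients)
    problems <- lapply(ccs, function(cc)
      build_nra_problem(cc, net, conc_fold = conc_fold, up_fold = up_fold,
                        max_interventions = max_interventions,
                        growth_drop_max = growth_drop_max))
    enumerations <- lapply(problems, enumerate_designs,
                           tolerance = tolerance, max_designs = 12)
    ranked <- rank_designs(enumerations, problems, top_k = top_k)
  }
  list(net = net, ground_truth = gt, config = config, data = data,
       models = models, screening = scr, retained = retained,
       problems = problems, enumerations = enumerations, ranked = ranked)
}

#' Compare constrained NRA designs with unconstrained top-k MCA designs
#'
#' Implements the phenotype-perturbation comparison: for each model, (a) the
#' NRA design under proximity constraints (bounded concentration fold
#' change, bounded growth drop), and (b) the naive strategy of applying a
#' fixed fold change to the top-k enzymes ranked by absolute yield control
#' coefficient, with no constraints. Both are simulated in batch, and final
#' biomass is reported relative to the unmodified reference strain.
#'
#' @param models list of (screened) `kinetic_model`.
#' @param net the `metabolic_network`.
#' @param config a [bioreactor_config()].
#' @param conc_fold NRA concentration proximity bound (default 3).
#' @param mca_fold fold change applied to the top-k MCA targets (default 5).
#' @param k number of MCA targets (default 3).
#' @return data.frame per model: relative growth (final biomass / reference
#'   final biomass) and final product titers for both strategies.
#' @export
compare_mca_nra <- function(models, net, config, conc_fold = 3,
                            mca_fold = 5, k = 3) {
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    ref <- simulate_batch(m, config)
    cc <- control_coefficients(m)
    nra_d <- solve_nra(build_nra_problem(cc, net, conc_fold = conc_fold))
    tr_nra <- simulate_batch(apply_design(m, nra_d$interventions), config)
    top <- top_k_targets(cc, "yield", k)
    mca_design <- data.frame(enzyme = top$enzyme, direction = top$direction,
                             fold = mca_fold)
    tr_mca <- simulate_batch(apply_design(m, mca_design), config)
    data.frame(model = i,
               ref_biomass = final_biomass(ref),
               nra_rel_growth = final_biomass(tr_nra) / final_biomass(ref),
               mca_rel_growth = final_biomass(tr_mca) / final_biomass(ref),
               nra_titer = final_titer(tr_nra),
               mca_titer = final_titer(tr_mca),
               ref_titer = final_titer(ref))
  })
  do.call(rbind, rows)
}
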