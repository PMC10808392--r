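# Shared fixtures, built lazily and cached for the whole test session.
.fixtures <- new.env(parent = emptyenv())

fix <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fb_net <- function() fix("fb_net", function() make_toy_network("feedback_branch"))
fb_thermo <- function() fix("fb_thermo", function() make_toy_thermo(fb_net()))
fb_bounds <- function() fix("fb_bounds", function() make_toy_flux_bounds(fb_net()))

fb_profiles <- function() fix("fb_profiles", function()
  sample_steady_states(fb_net(), fb_thermo(), fb_bounds(), n = 3, seed = 7))

# small ensemble, stability-pruned
fb_models <- function() fix("fb_models", function()
  suppressWarnings(sample_kinetic_models(fb_net(), fb_thermo(), fb_profiles(),
                                         per_profile = 4, seed = 11)))

fb_model <- function() fb_models()[[1]]

fb_gt <- function() fix("fb_gt", function()
  make_ground_truth_model(fb_net(), seed = 5))

fb_config <- function() fix("fb_config", function()
  make_toy_bioreactor_config(fb_gt()$model))

fb_data <- function() fix("fb_data", function()
  generate_pseudo_experiment(fb_gt()$model, fb_config(), noise_cv = 0.05,
                             seed = 2))

chain_gt <- function() fix("chain_gt", function()
  make_ground_truth_model(make_toy_network("chain"), seed = 3))

# internal steady state after modifying a model: relax the intracellular ODE
# and read the flux vector / growth at the new state
relax_to_steady_state <- function(model, t_end = 50) {
  ids <- rownames(stoichiometric_matrix(model$net, "internal"))
  out <- strainkin:::integrate_internal(model, model$anchor$ln_conc[ids], t_end)
  lnf <- model$anchor$ln_conc
  lnf[ids] <- as.numeric(out[nrow(out), -1])
  list(ln_conc = lnf, fluxes = evaluate_rate(model, lnf))
}
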