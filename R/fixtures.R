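#' Toy networks for pipeline testing
#'
#' Generates small, fully specified metabolic networks ("desk-scale"
#' stand-ins for a reduced genome-scale model) so that every pipeline stage
#' -- thermodynamic sampling, kinetic-ensemble generation, screening, control
#' analysis, intervention design and bioreactor simulation -- can be
#' exercised without any external data. All topologies route carbon from a
#' glucose-like substrate to an excreted product (an "anthranilate analog")
#' and a lumped biomass drain.
#'
#' Topologies:
#' \describe{
#'   \item{chain}{a linear pathway with `n_steps` enzymatic conversions,
#'     uptake and export transports (the final export crosses a periplasm
#'     compartment) and a biomass drain on an early intermediate.}
#'   \item{branched10}{ten reactions with a branch/reconvergence motif and no
#'     regulation; used for flux-variability and rank checks.}
#'   \item{feedback_branch}{a branch-point network in which the product
#'     branch entry (`BR1`) is competitively inhibited by the end product
#'     `F` of the competing branch -- the planted bottleneck. Biomass
#'     requires both branches, and an ATP/ADP pair adds a conserved moiety.}
#'   \item{bistable_toy}{a self-activating production loop (cooperative
#'     activation, Hill 2) with linear degradation; it has two stable states
#'     and intentionally fails the large-perturbation robustness screen.}
#'   \item{carbon_closed}{a closed-carbon pathway (no source exchange) with
#'     integer carbon counts attached as attributes, for elemental audits.}
#' }
#'
#' @param topology one of `"chain"`, `"branched10"`, `"feedback_branch"`,
#'   `"bistable_toy"`, `"carbon_closed"`.
#' @param n_steps chain length for `topology = "chain"`.
#' @return a `metabolic_network`; for `carbon_closed` the attributes
#'   `carbon` (mol C per mol metabolite) and `carbon_biomass` (mol C fixed
#'   into biomass per unit biomass flux) are set.
#' @export
make_toy_network <- function(topology = c("chain", "branched10",
                                          "feedback_branch", "bistable_toy",
                                          "carbon_closed"),
                             n_steps = 5) {
  topology <- match.arg(topology)
  met <- function(id, comp, bnd = FALSE)
    data.frame(id = id, name = id, compartment = comp, is_boundary = bnd,
               stringsAsFactors = FALSE)
  rxn <- function(id, rev = TRUE, transport = FALSE, exchange = FALSE)
    data.frame(id = id, reversible = rev, is_transport = transport,
               is_exchange = exchange, gene_label = NA_character_,
               stringsAsFactors = FALSE)

  if (topology == "chain") {
    stopifnot(n_steps >= 2)
    mids <- if (n_steps > 1) paste0("m", seq_len(n_steps - 1)) else character(0)
    mets <- rbind(met("glc_e", "e", TRUE), met("glc_c", "c"),
                  do.call(rbind, lapply(mids, met, comp = "c")),
                  met("ant_c", "c"), met("ant_p", "p"), met("ant_e", "e", TRUE))
    chain_nodes <- c("glc_c", mids, "ant_c")
    rxns <- rbind(rxn("EX_glc", rev = FALSE, exchange = TRUE),
                  rxn("UPT", transport = TRUE),
                  do.call(rbind, lapply(seq_len(n_steps),
                                        function(i) rxn(paste0("S", i)))),
                  rxn("TRA", transport = TRUE),
                  rxn("TRP", transport = TRUE),
                  rxn("EX_ant", rev = FALSE, exchange = TRUE),
                  rxn("BIO", rev = FALSE))
    stoich <- c(list(EX_glc = c(glc_e = 1), UPT = c(glc_e = -1, glc_c = 1)),
                stats::setNames(lapply(seq_len(n_steps), function(i)
                  stats::setNames(c(-1, 1),
                                  c(chain_nodes[i], chain_nodes[i + 1]))),
                  paste0("S", seq_len(n_steps))),
                list(TRA = c(ant_c = -1, ant_p = 1),
                     TRP = c(ant_p = -1, ant_e = 1),
                     EX_ant = c(ant_e = -1),
                     BIO = stats::setNames(-2, chain_nodes[2])))
    return(metabolic_network(mets, rxns, stoich, compartments = c("c", "p", "e"),
                             biomass_reaction = "BIO",
                             objective_product = "EX_ant",
                             substrate_uptake = "UPT"))
  }

  if (topology == "branched10") {
    mets <- rbind(met("s_e", "e", TRUE), met("s_c", "c"), met("A", "c"),
                  met("B", "c"), met("C", "c"), met("D", "c"),
                  met("p_e", "e", TRUE))
    rxns <- rbind(rxn("EX_s", rev = FALSE, exchange = TRUE),
                  rxn("UPT", transport = TRUE),
                  rxn("R1"), rxn("R2"), rxn("R3"), rxn("R4"), rxn("R5"),
                  rxn("TR_p", transport = TRUE),
                  rxn("EX_p", rev = FALSE, exchange = TRUE),
                  rxn("BIO", rev = FALSE))
    stoich <- list(EX_s = c(s_e = 1), UPT = c(s_e = -1, s_c = 1),
                   R1 = c(s_c = -1, A = 1), R2 = c(A = -1, B = 1),
                   R3 = c(A = -1, C = 1), R4 = c(B = -1, D = 1),
                   R5 = c(C = -1, D = 1), TR_p = c(D = -1, p_e = 1),
                   EX_p = c(p_e = -1), BIO = c(B = -2))
    return(metabolic_network(mets, rxns, stoich, compartments = c("c", "e"),
                             biomass_reaction = "BIO",
                             objective_product = "EX_p",
                             substrate_uptake = "UPT"))
  }

  if (topology == "feedback_branch") {
    mets <- rbind(met("glc_e", "e", TRUE), met("glc_c", "c"),
                  met("atp", "c"), met("adp", "c"),
                  met("A", "c"), met("B", "c"), met("C", "c"),
                  met("F", "c"),
                  met("ant_c", "c"), met("ant_p", "p"), met("ant_e", "e", TRUE))
    rxns <- rbind(rxn("EX_glc", rev = FALSE, exchange = TRUE),
                  rxn("UPT", transport = TRUE),
                  rxn("HEX"), rxn("RGN"), rxn("R2"),
                  rxn("BR1"), rxn("R3"), rxn("BR2"),
                  rxn("TRA", transport = TRUE),
                  rxn("TRP", transport = TRUE),
                  rxn("EX_ant", rev = FALSE, exchange = TRUE),
                  rxn("BIO", rev = FALSE))
    stoich <- list(EX_glc = c(glc_e = 1),
                   UPT = c(glc_e = -1, glc_c = 1),
                   HEX = c(glc_c = -1, atp = -1, A = 1, adp = 1),
                   RGN = c(adp = -1, atp = 1),
                   R2 = c(A = -1, B = 1),
                   BR1 = c(B = -1, C = 1),
                   R3 = c(C = -1, ant_c = 1),
                   BR2 = c(B = -1, F = 1),
                   TRA = c(ant_c = -1, ant_p = 1),
                   TRP = c(ant_p = -1, ant_e = 1),
                   EX_ant = c(ant_e = -1),
                   BIO = c(A = -2, F = -2))
    regs <- data.frame(regulator = "F", target = "BR1",
                       mode = "competitive_inhibition",
                       stringsAsFactors = FALSE)
    return(metabolic_network(mets, rxns, stoich, regulations = regs,
                             compartments = c("c", "p", "e"),
                             biomass_reaction = "BIO",
                             objective_product = "EX_ant",
                             substrate_uptake = "UPT"))
  }

  if (topology == "bistable_toy") {
    mets <- rbind(met("a_e", "e", TRUE), met("x_c", "c"), met("b_e", "e", TRUE))
    rxns <- rbind(rxn("EX_a", rev = FALSE, exchange = TRUE),
                  rxn("R_prod", rev = FALSE),
                  rxn("R_deg"),
                  rxn("EX_b", rev = FALSE, exchange = TRUE))
    stoich <- list(EX_a = c(a_e = 1), R_prod = c(a_e = -1, x_c = 1),
                   R_deg = c(x_c = -1, b_e = 1), EX_b = c(b_e = -1))
    regs <- data.frame(regulator = "x_c", target = "R_prod",
                       mode = "activation", hill = 2,
                       stringsAsFactors = FALSE)
    return(metabolic_network(mets, rxns, stoich, regulations = regs,
                             compartments = c("c", "e"),
                             biomass_reaction = "R_deg",
                             objective_product = "EX_b",
                             substrate_uptake = "EX_a"))
  }

  # carbon_closed: no source exchange; carbon audit attributes attached
  mets <- rbind(met("glc_e", "e", TRUE), met("glc_c", "c"),
                met("pyr", "c"), met("ant_c", "c"), met("ant_e", "e", TRUE))
  rxns <- rbind(rxn("UPT", transport = TRUE),
                rxn("GLY"), rxn("R3"),
                rxn("TRA", transport = TRUE),
                rxn("BIO", rev = FALSE))
  stoich <- list(UPT = c(glc_e = -1, glc_c = 1),
                 GLY = c(glc_c = -1, pyr = 2),
                 R3 = c(pyr = -1, ant_c = 1),
                 TRA = c(ant_c = -1, ant_e = 1),
                 BIO = c(pyr = -2))
  net <- metabolic_network(mets, rxns, stoich, compartments = c("c", "e"),
                           biomass_reaction = "BIO",
                           objective_product = "TRA",
                           substrate_uptake = "UPT")
  attr(net, "carbon") <- c(glc_e = 6, glc_c = 6, pyr = 3, ant_c = 3, ant_e = 3)
  attr(net, "carbon_biomass") <- 6   # 2 pyruvate-like C3 units per unit flux
  net
}

#' Default thermodynamic data for a toy network
#'
#' Assigns standard transformed Gibbs energies to every enzymatic and
#' transport reaction (exchanges and the biomass lump carry no thermodynamic
#' constraint), physiological concentration bounds, and the gas-constant
#' temperature product. Negative standard energies in the nominal pathway
#' direction keep the toy pathways thermodynamically open.
#'
#' @param net a `metabolic_network`.
#' @param dG0 standard Gibbs energy (kcal/mol) given to each constrained
#'   reaction in its nominal direction.
#' @param conc_lo,conc_hi default metabolite concentration bounds (mol/L).
#' @return a `thermo_data` list: `dG0`, `conc_bounds` (2-column matrix),
#'   `RT` (kcal/mol), `displacement_floor` (empty by default).
#' @export
make_toy_thermo <- function(net, dG0 = -2, conc_lo = 1e-6, conc_hi = 0.01) {
  rx <- net$reactions
  constrained <- rx$id[!rx$is_exchange & rx$id != net$biomass_reaction]
  dg <- stats::setNames(rep(dG0, length(constrained)), constrained)
  # boundary carriers (uptake, export) are strongly displaced, PTS-like
  comp_of <- stats::setNames(net$metabolites$compartment, net$metabolites$id)
  carrier <- constrained[vapply(constrained, function(rid)
    isTRUE(rx$is_transport[rx$id == rid]) &&
      any(comp_of[names(net$stoichiometry[[rid]])] == "e"), TRUE)]
  dg[carrier] <- -5
  cb <- matrix(rep(c(conc_lo, conc_hi), each = nrow(net$metabolites)),
               ncol = 2, dimnames = list(net$metabolites$id, c("lo", "hi")))
  # boundary species are pinned: a defined medium (substrate 0.02 mol/L,
  # i.e. a few g/L of a glucose-like carbon source; product initially
  # absent) so batch media equal the anchor and substrate exhaustion occurs
  # within a realistic fermentation horizon
  sub <- intersect(c("glc_e", "s_e", "a_e"), rownames(cb))
  prod <- intersect(c("ant_e", "p_e", "b_e"), rownames(cb))
  cb[sub, ] <- 0.02
  cb[prod, ] <- 1e-6
  # keep every toy enzyme meaningfully displaced from equilibrium so the
  # sampled ensembles are not dominated by near-equilibrium stiffness
  floor <- stats::setNames(rep(0.1, length(constrained)), constrained)
  structure(list(dG0 = dg, conc_bounds = cb, RT = 0.5925,
                 displacement_floor = floor),
            class = "thermo_data")
}

#' Default flux bounds for a toy network
#'
#' Uptake-limiting bounds: the source exchange (and the uptake transport) are
#' capped at `uptake_max`; all other reactions get wide bounds, one-sided for
#' irreversible reactions.
#'
#' @param net a `metabolic_network`.
#' @param uptake_max cap on substrate supply (mmol/gDW/h).
#' @param vmax generic flux cap.
#' @return 2-column matrix of lower/upper bounds, rows named by reaction.
#' @export
make_toy_flux_bounds <- function(net, uptake_max = 3, vmax = 50) {
  rx <- net$reactions
  fb <- matrix(0, nrow(rx), 2, dimnames = list(rx$id, c("lb", "ub")))
  fb[, "ub"] <- vmax
  fb[, "lb"] <- ifelse(rx$reversible, -vmax, 0)
  supply <- intersect(c("EX_glc", "EX_s", "EX_a"), rx$id)
  fb[c(supply, net$substrate_uptake), "ub"] <- uptake_max
  fb[net$substrate_uptake, "lb"] <- 0
  # the reference strain secretes product: keep the product pathway alive in
  # every sampled steady state (a tenth of the substrate cap) by flooring
  # the reactions that actually produce the excreted product species
  prod_sp <- {
    s <- net$stoichiometry[[net$objective_product]]
    intersect(names(s), net$metabolites$id[net$metabolites$is_boundary])[1]
  }
  feeders <- rx$id[vapply(rx$id, function(rid) {
    s <- net$stoichiometry[[rid]]
    !isTRUE(rx$is_exchange[rx$id == rid]) &&
      prod_sp %in% names(s) && s[[prod_sp]] > 0
  }, TRUE)]
  fb[c(net$objective_product, feeders), "lb"] <- uptake_max / 10
  fb
}

#' Default batch-reactor configuration for a toy network
#'
#' Medium concentrations equal the anchor boundary concentrations (so the
#' consistency property "simulated rates at t = 0 equal anchor fluxes"
#' holds), a small inoculum, and glucose/anthranilate-like molar masses for
#' g/L reporting.
#'
#' @param model a `kinetic_model`.
#' @param initial_biomass inoculum gDW/L.
#' @param t_end horizon in hours.
#' @param include_dilution intracellular dilution term; off by default here
#'   so the toy anchor is an exact exponential-phase steady state.
#' @return a [bioreactor_config()].
#' @export
make_toy_bioreactor_config <- function(model, initial_biomass = 0.05,
                                       t_end = 20, include_dilution = FALSE) {
  net <- model$net
  bnd <- boundary_met_ids(net)
  medium <- exp(model$anchor$ln_conc[bnd])
  mm <- stats::setNames(rep(NA_real_, length(bnd)), bnd)
  mm[grep("^glc|^s_", bnd)] <- 180
  mm[grep("^ant|^p_|^b_", bnd)] <- 137
  mm <- mm[!is.na(mm)]
  # the toy anchor is the exponential-phase state: without the dilution term
  # it is an exact intracellular steady state, so growth holds at the anchor
  # rate until substrate exhaustion and the screening thresholds behave as
  # designed; the dilution convention is exercised where it is exact (the
  # closed-carbon audit)
  bioreactor_config(initial_biomass = initial_biomass, medium = medium,
                    t_end = t_end, molar_mass = mm,
                    include_dilution = include_dilution)
}

#' Ground-truth kinetic model for a toy network
#'
#' Samples one thermodynamically consistent steady state and one stable,
#' fast-relaxing kinetic parameter set (dominant time constant below one
#' fifth of the doubling time, resampling until the criteria are met), so
#' that downstream screens pass by construction. The `bistable_toy`
#' topology is special-cased with a hand-picked saturation state that
#' anchors the model on the upper branch of its bistable production loop.
#'
#' @param net from [make_toy_network()].
#' @param seed RNG seed; fixture bundles are reproducible.
#' @param thermo,flux_bounds optional overrides of the toy defaults.
#' @param max_tries resampling budget before giving up.
#' @return list with `model` (a `kinetic_model`), `profile`, `thermo`,
#'   `flux_bounds`.
#' @export
make_ground_truth_model <- function(net, seed = 1, thermo = NULL,
                                    flux_bounds = NULL, max_tries = 60) {
  if (is.null(thermo)) thermo <- make_toy_thermo(net)
  if (is.null(flux_bounds)) flux_bounds <- make_toy_flux_bounds(net)

  if ("R_prod" %in% net$reactions$id && "x_c" %in% net$metabolites$id) {
    # bistable toy: fixed anchor on the upper stable state
    thermo$dG0[c("R_prod", "R_deg")] <- -5
    ln <- c(a_e = log(2e-2), x_c = log(1e-3), b_e = log(1e-6))
    fl <- c(EX_a = 1, R_prod = 1, R_deg = 1, EX_b = 1)
    dG <- stats::setNames(rep(NA_real_, 4), names(fl))
    for (rid in c("R_prod", "R_deg")) {
      s <- net$stoichiometry[[rid]]
      dG[rid] <- thermo$dG0[[rid]] + thermo$RT * sum(s * ln[names(s)])
    }
    profile <- structure(list(fluxes = fl, ln_conc = ln, dG = dG,
                              growth_rate = 1),
                         class = "steady_state_profile")
    assignment <- assign_rate_laws(net)
    sat <- list(sites = list(EX_a = numeric(0),
                             R_prod = c(a_e = 0.5, x_c = 0.01),
                             R_deg = c(x_c = 0.05, b_e = 0.5),
                             EX_b = numeric(0)),
                reg = 2 / 3)
    params <- parameterize_from_saturation(net, assignment, profile, thermo,
                                           sat)
    model <- kinetic_model(net, assignment, params, profile)
    return(list(model = model, profile = profile, thermo = thermo,
                flux_bounds = flux_bounds))
  }

  assignment <- assign_rate_laws(net)
  for (try in seq_len(max_tries)) {
    profiles <- tryCatch(
      sample_steady_states(net, thermo, flux_bounds, n = 1,
                           seed = seed + 1000L * (try - 1L)),
      warning = function(w) list(), error = function(e) list())
    if (length(profiles) == 0) next
    profile <- profiles[[1]]
    thr <- doubling_time(profile$growth_rate) / 5 / 60        # hours
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed + 1000L * (try - 1L))
    for (att in 1:40) {
      sat <- sample_saturations(net, assignment)
      params <- parameterize_from_saturation(net, assignment, profile,
                                             thermo, sat)
      model <- kinetic_model(net, assignment, params, profile)
      es <- eigen_summary(model)
      if (es$stable && es$tau_d < thr) {
        if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
        return(list(model = model, profile = profile, thermo = thermo,
                    flux_bounds = flux_bounds))
      }
    }
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  stop("could not construct a ground-truth model within the attempt budget")
}

#' Generate pseudo-experimental fermentation curves
#'
#' Simulates a batch fermentation with the ground-truth model, subsamples
#' about `n_points` time points, and adds multiplicative Gaussian noise with
#' coefficient of variation `noise_cv` per replicate. Reported units follow
#' the config's molar masses (g/L).
#'
#' @param model a `kinetic_model`.
#' @param config a [bioreactor_config()].
#' @param noise_cv multiplicative noise CV (0 gives the noiseless curves).
#' @param n_replicates replicates averaged into the mean/sd table.
#' @param seed RNG seed.
#' @param n_points number of sampled time points.
#' @return data.frame: time, biomass, substrate, product (replicate means)
#'   and their `_sd` columns.
#' @export
generate_pseudo_experiment <- function(model, config, noise_cv = 0.05,
                                       n_replicates = 3, seed = 1,
                                       n_points = 10) {
  traj <- simulate_batch(model, config)
  idx <- unique(round(seq(1, length(traj$time), length.out = n_points)))
  mm <- config$molar_mass
  scale_of <- function(id) if (id %in% names(mm)) mm[[id]] else 1
  truth <- data.frame(time = traj$time[idx],
                      biomass = traj$biomass[idx],
                      substrate = traj$conc[idx, traj$substrate] *
                        scale_of(traj$substrate),
                      product = traj$conc[idx, traj$product] *
                        scale_of(traj$product))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  reps <- lapply(seq_len(n_replicates), function(r) {
    noisy <- truth
    for (col in c("biomass", "substrate", "product"))
      noisy[[col]] <- truth[[col]] *
        (1 + noise_cv * stats::rnorm(nrow(truth)))
    noisy
  })
  out <- truth
  for (col in c("biomass", "substrate", "product")) {
    M <- sapply(reps, `[[`, col)
    out[[col]] <- rowMeans(M)
    out[[paste0(col, "_sd")]] <- apply(M, 1, stats::sd)
  }
  out
}

#' Write a complete fixture bundle to a directory
#'
#' Network (TSV and SBML), thermodynamic data and flux bounds (CSV),
#' pseudo-experimental curves (CSV) and the run configuration (YAML) for a
#' chosen topology -- everything the pipeline needs, generated in code.
#'
#' @param topology see [make_toy_network()].
#' @param seed RNG seed.
#' @param dir output directory.
#' @param noise_cv pseudo-experiment noise.
#' @return the directory, invisibly.
#' @export
write_fixture_bundle <- function(topology, seed, dir, noise_cv = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_toy_network(topology)
  gt <- make_ground_truth_model(net, seed = seed)
  write_network(net, file.path(dir, "network"), "tsv")
  write_network(net, file.path(dir, "network.xml"), "sbml")
  utils::write.csv(data.frame(reaction = names(gt$thermo$dG0),
                              dG0 = unname(gt$thermo$dG0)),
                   file.path(dir, "dG0.csv"), row.names = FALSE)
  utils::write.csv(data.frame(metabolite = rownames(gt$thermo$conc_bounds),
                              lo = gt$thermo$conc_bounds[, 1],
                              hi = gt$thermo$conc_bounds[, 2]),
                   file.path(dir, "conc_bounds.csv"), row.names = FALSE)
  utils::write.csv(data.frame(reaction = rownames(gt$flux_bounds),
                              lb = gt$flux_bounds[, 1],
                              ub = gt$flux_bounds[, 2]),
                   file.path(dir, "flux_bounds.csv"), row.names = FALSE)
  config <- make_toy_bioreactor_config(gt$model)
  curves <- generate_pseudo_experiment(gt$model, config, noise_cv = noise_cv,
                                       seed = seed)
  utils::write.csv(curves, file.path(dir, "curves.csv"), row.names = FALSE)
  yaml::write_yaml(list(topology = topology, seed = seed,
                        initial_biomass = config$initial_biomass,
                        t_end = config$t_end,
                        medium = as.list(config$medium),
                        molar_mass = as.list(config$molar_mass),
                        rtol = config$rtol, atol = config$atol),
                   file.path(dir, "config.yaml"))
  write_model_json(gt$model, file.path(dir, "ground_truth_model.json"))
  invisible(dir)
}
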