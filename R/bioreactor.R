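#' Batch bioreactor configuration
#'
#' @param initial_biomass inoculum, gDW/L.
#' @param medium named numeric, mol/L, covering every boundary species.
#' @param t_end simulated fermentation horizon, h.
#' @param rtol,atol stiff-integrator tolerances (default 1e-8 / 1e-10; model
#'   screening depends on accurate relaxation).
#' @param molar_mass named numeric g/mol for species whose titers are
#'   reported in g/L (others are reported in mol/L).
#' @param include_dilution include the growth-dilution term `-mu * x` on
#'   intracellular species (default TRUE).
#' @param exhaustion_frac substrate fraction of the initial value below
#'   which the fermentation is considered finished (default 1%).
#' @return a `bioreactor_config`.
#' @export
bioreactor_config <- function(initial_biomass, medium, t_end = 20,
                              rtol = 1e-8, atol = 1e-10,
                              molar_mass = numeric(0),
                              include_dilution = TRUE,
                              exhaustion_frac = 0.01) {
  stopifnot(initial_biomass >= 0, t_end > 0)
  structure(list(initial_biomass = initial_biomass, medium = medium,
                 t_end = t_end, rtol = rtol, atol = atol,
                 molar_mass = molar_mass,
                 include_dilution = include_dilution,
                 exhaustion_frac = exhaustion_frac),
            class = "bioreactor_config")
}

# species roles for titer bookkeeping
product_species <- function(net) {
  s <- net$stoichiometry[[net$objective_product]]
  ids <- intersect(names(s), boundary_met_ids(net))
  if (length(ids) == 0) stop("objective product reaction touches no boundary species")
  ids[1]
}

substrate_species <- function(net) {
  s <- net$stoichiometry[[net$substrate_uptake]]
  ids <- intersect(names(s)[s < 0], boundary_met_ids(net))
  if (length(ids) == 0) stop("uptake reaction consumes no boundary species")
  ids[1]
}

#' Simulate a batch fermentation
#'
#' Couples the kinetic model to reactor-scale biomass and medium dynamics:
#' `dX/dt = mu X` with `mu` read from the biomass reaction's instantaneous
#' flux; boundary (medium) species evolve as `dc/dt = 0.001 X (N v)` over
#' the non-exchange reactions (exchange pseudo-reactions are the flux-balance
#' system boundary and do not act in a closed reactor); intracellular species
#' follow `dx/dt = f N v - mu x` (dilution term optional). At `t = 0` under
#' anchor conditions the instantaneous specific rates equal the anchor
#' fluxes.
#'
#' @param model a `kinetic_model`.
#' @param config a [bioreactor_config()]; `medium` must cover all boundary
#'   species.
#' @param n_out number of reporting time points.
#' @return a `trajectory`: `time` (h), `biomass` (g/L), `conc` (matrix,
#'   mol/L, boundary + internal species), plus the config and network roles
#'   used by the summary accessors.
#' @export
simulate_batch <- function(model, config, n_out = 200) {
  net <- model$net
  bnd <- boundary_met_ids(net)
  if (!all(bnd %in% names(config$medium)))
    stop("medium must cover boundary species: ",
         paste(setdiff(bnd, names(config$medium)), collapse = ", "))
  N_all <- stoichiometric_matrix(net, "all")
  nonex <- net$reactions$id[!net$reactions$is_exchange]
  N_bnd <- N_all[bnd, nonex, drop = FALSE]
  N_int <- stoichiometric_matrix(net, "internal")[, , drop = FALSE]
  int <- rownames(N_int)
  bio <- net$biomass_reaction
  dil <- isTRUE(config$include_dilution)

  y0 <- c(X = unname(config$initial_biomass),
          config$medium[bnd],
          exp(model$anchor$ln_conc[int]))
  cache <- build_rate_cache(model)
  state_pos <- match(cache$mets, c(bnd, int))   # metabolite -> state slot
  ln_anchor <- model$anchor$ln_conc[cache$mets]
  bio_i <- match(bio, cache$rids)
  rhs <- function(t, y, parms) {
    X <- y[1]
    conc <- pmax(y[-1], 1e-15)
    lnfull <- ln_anchor
    ok <- !is.na(state_pos)
    lnfull[ok] <- log(conc[state_pos[ok]])
    v <- evaluate_rate_cached(cache, lnfull)
    mu <- v[[bio_i]]
    dX <- mu * X
    dbnd <- 0.001 * X * drop(N_bnd %*% v[nonex])
    dint <- model$scale_int * drop(N_int %*% v[colnames(N_int)])
    if (dil) dint <- dint - mu * conc[int]
    list(c(dX, dbnd, dint))
  }
  times <- seq(0, config$t_end, length.out = n_out)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = config$rtol, atol = config$atol)
  if (attr(out, "istate")[1] < 0)
    stop("stiff integration failed at t = ", max(out[, 1]))
  conc <- out[, -(1:2), drop = FALSE]
  colnames(conc) <- c(bnd, int)
  structure(list(time = out[, 1], biomass = out[, 2], conc = conc,
                 config = config,
                 substrate = substrate_species(net),
                 product = product_species(net)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Batch trajectory:", length(x$time), "points over",
      max(x$time), "h | final biomass", signif(final_biomass(x), 4),
      "g/L | final product titer", signif(final_titer(x), 4), "\n")
  invisible(x)
}

#' Final biomass of a trajectory (g/L)
#' @param traj a `trajectory`.
#' @export
final_biomass <- function(traj) traj$biomass[length(traj$biomass)]

#' Final product titer of a trajectory
#' @param traj a `trajectory`.
#' @param species species id (default: the network's product species).
#' @return g/L if a molar mass is configured for the species, else mol/L.
#' @export
final_titer <- function(traj, species = traj$product) {
  v <- unname(traj$conc[nrow(traj$conc), species])
  mm <- traj$config$molar_mass
  if (species %in% names(mm)) v * unname(mm[[species]]) else v
}

#' Fermentation time: substrate-exhaustion time point
#'
#' First time at which the substrate falls below `exhaustion_frac` of its
#' initial value; `NA` if it never does within the horizon.
#' @param traj a `trajectory`.
#' @export
fermentation_time <- function(traj) {
  s <- traj$conc[, traj$substrate]
  thr <- traj$config$exhaustion_frac * s[1]
  i <- which(s < thr)
  if (length(i) == 0) NA_real_ else traj$time[min(i)]
}

#' Volumetric productivity: final titer over fermentation time
#' @param traj a `trajectory`.
#' @export
productivity <- function(traj) {
  ft <- fermentation_time(traj)
  if (is.na(ft)) ft <- max(traj$time)
  final_titer(traj) / ft
}

#' Write a trajectory as tidy long-format CSV
#' @param traj a `trajectory`; `path` output file.
#' @param path output CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  long <- rbind(data.frame(time = traj$time, species = "biomass",
                           value = traj$biomass),
                do.call(rbind, lapply(colnames(traj$conc), function(id)
                  data.frame(time = traj$time, species = id,
                             value = traj$conc[, id]))))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Apply an intervention design to a kinetic model
#'
#' Scales the maximal velocity (or mass-action rate constant) of each
#' targeted enzyme by its fold change -- multiplied for upregulation,
#' divided for downregulation. The anchor profile is kept as metadata; the
#' engineered model no longer anchors to it, by construction.
#'
#' @param model a `kinetic_model`.
#' @param design data.frame with columns `enzyme`, `direction`
#'   (`"up"`/`"down"`), `fold` (> 1); at most one direction per enzyme.
#' @return the modified `kinetic_model`.
#' @export
apply_design <- function(model, design) {
  if (nrow(design) == 0) return(model)
  if (anyDuplicated(design$enzyme))
    stop("a design may touch each enzyme in one direction only")
  bad <- setdiff(design$enzyme, names(model$params$k))
  if (length(bad)) stop("unknown enzyme(s): ", paste(bad, collapse = ", "))
  stopifnot(all(design$fold >= 1), all(design$direction %in% c("up", "down")))
  f <- ifelse(design$direction == "up", design$fold, 1 / design$fold)
  model$params$k[design$enzyme] <- model$params$k[design$enzyme] * f
  model
}

#' Edit a regulatory interaction on a model
#'
#' `action = "remove"` makes an inhibition (or activation) inert by setting
#' its constant to `1e12` times the regulator's anchor concentration -- for
#' inhibitors this can only increase the rate at any state; for activators
#' use `scale` instead. `action = "scale"` multiplies the constant by
#' `factor`.
#'
#' @param model a `kinetic_model`.
#' @param target reaction id; `regulator` metabolite id.
#' @param regulator metabolite id of the effector.
#' @param action `"remove"` or `"scale"`.
#' @param factor multiplier for `action = "scale"`.
#' @return the modified `kinetic_model`.
#' @export
edit_regulation <- function(model, target, regulator,
                            action = c("remove", "scale"), factor = NULL) {
  action <- match.arg(action)
  regs <- model$params$reg
  i <- which(regs$target == target & regs$regulator == regulator)
  if (length(i) == 0)
    stop("no regulation of ", target, " by ", regulator, " in this model")
  if (action == "remove") {
    model$params$reg$K[i] <- 1e12 * exp(model$anchor$ln_conc[[regulator]])
  } else {
    stopifnot(is.numeric(factor), factor > 0)
    model$params$reg$K[i] <- regs$K[i] * factor
  }
  model
}

#' Sensitivity of a design to expression uncertainty
#'
#' Starting from the mean fold change of each enzyme across the per-model
#' designs, draws perturbed fold changes uniformly in
#' `mean * (1 - spread, 1 + spread)` and simulates every (model, replicate)
#' combination in batch. `mode = "all"` perturbs all enzymes jointly;
#' `mode = "each"` perturbs one enzyme at a time with the others pinned at
#' their mean folds.
#'
#' @param models list of `kinetic_model`.
#' @param designs list (parallel to `models`) of design data.frames sharing
#'   one membership, or a single design recycled to all models.
#' @param config a [bioreactor_config()].
#' @param spread half-width of the uniform perturbation (default 0.5).
#' @param reps replicates per model (default 10).
#' @param mode `"all"` or `"each"`.
#' @param seed RNG seed.
#' @return list with `trials` (one row per trajectory: model, rep, perturbed
#'   enzyme, folds, final titer and biomass) and `mean_titer` (mean across
#'   all completed trials; for `mode = "each"`, per enzyme).
#' @export
sensitivity_analysis <- function(models, designs, config, spread = 0.5,
                                 reps = 10, mode = c("all", "each"),
                                 seed = 1) {
  mode <- match.arg(mode)
  if (is.data.frame(designs)) designs <- rep(list(designs), length(models))
  stopifnot(length(designs) == length(models))
  base <- designs[[1]][, c("enzyme", "direction")]
  # mean fold per enzyme across models
  folds <- sapply(base$enzyme, function(e)
    mean(vapply(designs, function(d) d$fold[d$enzyme == e], 0)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  perturb_sets <- if (mode == "all") list(base$enzyme) else as.list(base$enzyme)
  rows <- list()
  for (set_i in seq_along(perturb_sets)) {
    for (m in seq_along(models)) {
      for (r in seq_len(reps)) {
        f <- folds
        pe <- perturb_sets[[set_i]]
        f[pe] <- folds[pe] * stats::runif(length(pe), 1 - spread, 1 + spread)
        d <- data.frame(enzyme = base$enzyme, direction = base$direction,
                        fold = unname(f[base$enzyme]))
        titer <- tryCatch({
          traj <- simulate_batch(apply_design(models[[m]], d), config)
          c(final_titer(traj), final_biomass(traj))
        }, error = function(e) c(NA_real_, NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          perturbed = paste(pe, collapse = "+"), model = m, rep = r,
          titer = titer[1], biomass = titer[2])
      }
    }
  }
  trials <- do.call(rbind, rows)
  mean_titer <- c(tapply(trials$titer, trials$perturbed, mean, na.rm = TRUE))
  list(trials = trials, mean_titer = mean_titer,
       n_failed = sum(is.na(trials$titer)))
}

#' Cluster intervention designs by enzyme membership
#'
#' Hierarchical agglomerative clustering (average linkage) on the binary
#' enzyme-membership vectors with Jaccard distance; deterministic.
#'
#' @param designs list of character vectors (enzyme sets, optionally with
#'   direction suffixes).
#' @param n_clusters optional cut level.
#' @return list with `assignment` (integer vector), `hclust` object and the
#'   membership `matrix`.
#' @export
cluster_designs <- function(designs, n_clusters = NULL) {
  stopifnot(length(designs) >= 2)
  enz <- sort(unique(unlist(designs)))
  M <- t(vapply(designs, function(d) as.numeric(enz %in% d),
                numeric(length(enz))))
  colnames(M) <- enz
  if (nrow(unique(M)) == 1)
    return(list(assignment = rep(1L, length(designs)), hclust = NULL,
                matrix = M))
  D <- stats::dist(M, method = "binary")      # Jaccard distance on 0/1 rows
  hc <- stats::hclust(D, method = "average")
  k <- if (is.null(n_clusters)) max(1L, length(unique(round(hc$height, 10))))
       else n_clusters
  if (!is.null(n_clusters)) {
    assignment <- stats::cutree(hc, k = n_clusters)
  } else {
    # default cut: largest gap in merge heights
    h <- sort(unique(hc$height))
    if (length(h) == 1) {
      assignment <- stats::cutree(hc, h = h / 2)
    } else {
      gaps <- diff(h)
      cut_h <- h[which.max(gaps)] + max(gaps) / 2
      assignment <- stats::cutree(hc, h = cut_h)
    }
  }
  list(assignment = assignment, hclust = hc, matrix = M)
}

#' Rank designs by nonlinear batch performance
#'
#' Simulates every design on every model (using each model's own suggested
#' fold changes where provided) and ranks by median final titer across
#' models, tie-broken by median productivity.
#'
#' @param models list of `kinetic_model`.
#' @param designs list of designs; each either a single data.frame applied
#'   to all models or a list of per-model data.frames.
#' @param config a [bioreactor_config()].
#' @return data.frame (one row per design, ranked): median/IQR titer,
#'   median productivity, median time to 90% of maximal titer.
#' @export
rank_designs_nonlinear <- function(models, designs, config) {
  rows <- lapply(seq_along(designs), function(di) {
    d <- designs[[di]]
    per_model <- if (is.data.frame(d)) rep(list(d), length(models)) else d
    tit <- pro <- t90 <- rep(NA_real_, length(models))
    for (m in seq_along(models)) {
      traj <- tryCatch(simulate_batch(apply_design(models[[m]], per_model[[m]]),
                                      config),
                       error = function(e) NULL)
      if (is.null(traj)) next
      tit[m] <- final_titer(traj)
      pro[m] <- productivity(traj)
      mm <- traj$config$molar_mass
      pser <- traj$conc[, traj$product] *
        (if (traj$product %in% names(mm)) mm[[traj$product]] else 1)
      t90[m] <- traj$time[min(which(pser >= 0.9 * max(pser)))]
    }
    data.frame(design = di,
               label = paste(
                 paste0(per_model[[1]]$enzyme,
                        ifelse(per_model[[1]]$direction == "up", "+", "-")),
                 collapse = ","),
               median_titer = stats::median(tit, na.rm = TRUE),
               iqr_titer = stats::IQR(tit, na.rm = TRUE),
               median_productivity = stats::median(pro, na.rm = TRUE),
               median_t90 = stats::median(t90, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  out[order(-out$median_titer, -out$median_productivity, out$label), ]
}
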