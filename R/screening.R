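#' Reduced Jacobian of a kinetic model at its anchor
#'
#' Jacobian of the intracellular dynamics `dx/dt = f * N v(x)` with respect
#' to the independent internal species, evaluated at the anchor steady
#' state. Conserved-moiety directions are removed with the link matrix, so
#' the structural zero eigenvalues they would contribute do not pollute the
#' spectrum.
#'
#' @param model a `kinetic_model`.
#' @return square matrix (independent internal species), units 1/h.
#' @export
compute_jacobian <- function(model) {
  lm <- link_matrix(model$net)
  re <- rate_and_elasticity(model, model$anchor$ln_conc)
  x <- exp(model$anchor$ln_conc)
  # d v_k / d x_j = v_k * E_kj / x_j  (valid at the anchor, where every
  # reaction either carries flux or has a zero maximal rate)
  dvdx <- re$v * re$E[, rownames(lm$L), drop = FALSE]
  dvdx <- sweep(dvdx, 2, x[rownames(lm$L)], "/")
  J <- model$scale_int * (lm$NR %*% dvdx %*% lm$L)
  unname(J)
}

#' Eigenvalue summary of a model's linearized dynamics
#'
#' @param model a `kinetic_model`.
#' @return an `eigen_summary`: eigenvalues (1/h), `stable`, dominant time
#'   constant `tau_d` (h, `NA` if unstable) and the count of structural
#'   zeros excluded by the link reduction.
#' @export
eigen_summary <- function(model) {
  lm <- link_matrix(model$net)
  J <- compute_jacobian(model)
  ev <- eigen(J, only.values = TRUE)$values
  stable <- all(Re(ev) < 0)
  structure(list(eigenvalues = ev,
                 stable = stable,
                 tau_d = if (stable) dominant_time_constant(ev) else NA_real_,
                 n_structural_zeros = length(lm$dep)),
            class = "eigen_summary")
}

#' Dominant time constant from a Jacobian spectrum
#'
#' The slowest relaxation timescale, `tau_d = 1 / min_i |Re(lambda_i)|`.
#' If any eigenvalue has a non-negative real part the model is unstable and
#' `NA` is returned with attribute `stable = FALSE` (a flag, not an error).
#'
#' @param eig complex eigenvalues (conserved-moiety zeros already excluded).
#' @return time constant in the inverse units of the eigenvalues.
#' @export
dominant_time_constant <- function(eig) {
  if (any(Re(eig) >= 0)) {
    out <- NA_real_
    attr(out, "stable") <- FALSE
    return(out)
  }
  1 / min(abs(Re(eig)))
}

#' Fraction of a perturbation recovered after time t
#'
#' First-order relaxation recovers `1 - exp(-t / tau)` of an initial
#' deviation; five dominant time constants recover 99.3%.
#'
#' @param t elapsed time; `tau` the (dominant) time constant, same units.
#' @return value in (0, 1).
#' @export
recovery_fraction <- function(t, tau) {
  stopifnot(t > 0, tau > 0)
  1 - exp(-t / tau)
}

#' Doubling time in minutes from a specific growth rate
#'
#' @param mu growth rate in 1/h.
#' @return `ln(2)/mu`, expressed in minutes.
#' @export
doubling_time <- function(mu) {
  if (any(mu <= 0)) stop("growth rate must be positive")
  60 * log(2) / mu
}

#' Screen an ensemble by linearized dynamics
#'
#' Retains models that are locally stable and whose dominant time constant
#' is below `tau_max`. The default threshold is one fifth of the anchor
#' doubling time (responses then recover 99.3% of a perturbation within one
#' doubling), the generalization behind case-specific presets such as 24 or
#' 43 minutes.
#'
#' @param models list of `kinetic_model`.
#' @param tau_max threshold in hours; `NULL` uses doubling_time/5 per model.
#' @return list with `retained` (indices into `models`) and `summary`
#'   data.frame (stable, tau_d hours, threshold used).
#' @export
screen_linear_dynamics <- function(models, tau_max = NULL) {
  rows <- lapply(seq_along(models), function(i) {
    es <- eigen_summary(models[[i]])
    thr <- if (is.null(tau_max))
      doubling_time(models[[i]]$anchor$growth_rate) / 5 / 60 else tau_max
    data.frame(model = i, stable = es$stable, tau_d = es$tau_d,
               tau_max = thr,
               pass = es$stable && !is.na(es$tau_d) && es$tau_d < thr)
  })
  s <- do.call(rbind, rows)
  list(retained = s$model[s$pass], summary = s)
}

# integrate the intracellular subsystem in log-concentration space; boundary
# species stay at their anchor values
integrate_internal <- function(model, ln0, t_end, n_out = 60,
                               rtol = 1e-8, atol = 1e-10) {
  N <- stoichiometric_matrix(model$net, "internal")
  ids <- rownames(N)
  cache <- build_rate_cache(model)
  ln_anchor <- model$anchor$ln_conc[cache$mets]
  pos <- match(ids, cache$mets)
  Nv <- N[, cache$rids, drop = FALSE]
  rhs <- function(t, y, parms) {
    lnfull <- ln_anchor
    lnfull[pos] <- y
    v <- evaluate_rate_cached(cache, lnfull)
    dx <- model$scale_int * drop(Nv %*% v)
    list(dx / exp(y))
  }
  times <- seq(0, t_end, length.out = n_out)
  out <- deSolve::ode(y = ln0[ids], times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  out
}

#' Screen a model's robustness to nonlinear concentration perturbations
#'
#' Applies `n` random k-fold perturbations to the internal anchor
#' concentrations (each species independently multiplied or divided by
#' `k_fold`), integrates the intracellular ODEs, and requires every internal
#' species to come back within `tol_band` (relative) of the anchor by the
#' horizon.
#'
#' @param model a stable `kinetic_model`.
#' @param k_fold fold perturbation (1 = none).
#' @param n number of random trials.
#' @param horizon integration horizon in hours.
#' @param seed RNG seed (trial set is reproducible).
#' @param tol_band relative recovery band (default 1%).
#' @return TRUE if all trials recover; integrator failures count as fail.
#' @export
screen_concentration_robustness <- function(model, k_fold = 2, n = 10,
                                            horizon = NULL, seed = 1,
                                            tol_band = 0.01) {
  ids <- rownames(stoichiometric_matrix(model$net, "internal"))
  ln_ss <- model$anchor$ln_conc[ids]
  if (is.null(horizon))
    horizon <- doubling_time(model$anchor$growth_rate) / 60  # hours
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (trial in seq_len(n)) {
    u <- sample(c(-1, 1), length(ids), replace = TRUE)
    ln0 <- ln_ss + u * log(k_fold)
    out <- tryCatch(integrate_internal(model, ln0, horizon),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(out)) return(FALSE)
    fin <- out[nrow(out), -1]
    if (any(abs(exp(fin - ln_ss) - 1) > tol_band)) return(FALSE)
  }
  TRUE
}

#' Screen a model against batch fermentation data
#'
#' Simulates a batch fermentation (see [simulate_batch()]) and accepts the
#' model if the simulated final biomass and final product concentrations lie
#' within `tol_biomass` / `tol_product` (relative) of the data's final
#' values and the fermentation time (substrate exhaustion) is below `t_max`.
#'
#' @param model a `kinetic_model`.
#' @param data data.frame with columns `time` (h), `biomass` (g/L),
#'   `substrate`, `product` (concentration units matching the simulation's
#'   reporting, g/L when molar masses are configured).
#' @param config a [bioreactor_config()].
#' @param tol_biomass,tol_product relative tolerances (default 5% and 10%).
#' @param t_max fermentation-time cap in hours (default 20).
#' @return logical `pass` with attribute `metrics` (data.frame of the
#'   relative errors and the fermentation time).
#' @export
screen_fermentation_fit <- function(model, data, config,
                                    tol_biomass = 0.05, tol_product = 0.10,
                                    t_max = 20) {
  need <- c("time", "biomass", "substrate", "product")
  if (!all(need %in% names(data)))
    stop("fermentation data must have columns ", paste(need, collapse = ", "))
  if (is.unsorted(data$time, strictly = FALSE))
    stop("time column must be non-decreasing")
  traj <- simulate_batch(model, config)
  bio_err <- abs(final_biomass(traj) - data$biomass[nrow(data)]) /
    max(data$biomass[nrow(data)], 1e-12)
  prod_err <- abs(final_titer(traj) - data$product[nrow(data)]) /
    max(data$product[nrow(data)], 1e-12)
  ft <- fermentation_time(traj)
  pass <- (bio_err <= tol_biomass) && (prod_err <= tol_product) &&
    (!is.na(ft) && ft < t_max)
  attr(pass, "metrics") <- data.frame(biomass_rel_err = bio_err,
                                      product_rel_err = prod_err,
                                      fermentation_time = ft)
  pass
}

#' Screen a model's robustness to enzymatic perturbations
#'
#' Applies `n` independent perturbations in which every maximal velocity is
#' multiplied by `1 + N(0, cv^2)` draws, simulates each perturbed model in
#' batch, and requires the final biomass of every trial to reach at least
#' `growth_floor` times the unperturbed final biomass.
#'
#' @param model a `kinetic_model`.
#' @param config a [bioreactor_config()].
#' @param cv coefficient of variation of the Vmax perturbation (default 10%).
#' @param n number of trials (default 50).
#' @param growth_floor fraction of reference final biomass required.
#' @param seed RNG seed.
#' @return logical; integrator failures count as failed trials.
#' @export
screen_enzyme_robustness <- function(model, config, cv = 0.10, n = 50,
                                     growth_floor = 0.5, seed = 1) {
  ref <- tryCatch(final_biomass(simulate_batch(model, config)),
                  error = function(e) NA_real_)
  if (is.na(ref)) return(FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (trial in seq_len(n)) {
    f <- 1 + stats::rnorm(length(model$params$k), 0, cv)
    f[f < 0.01] <- 0.01
    pert <- model
    pert$params$k <- model$params$k * f
    fb <- tryCatch(final_biomass(simulate_batch(pert, config)),
                   error = function(e) NA_real_)
    if (is.na(fb) || fb < growth_floor * ref) return(FALSE)
  }
  TRUE
}

#' Full screening report for an ensemble
#'
#' Applies the linear-dynamics, fermentation-fit and enzyme-robustness
#' criteria (each a pure predicate on a model, so the outcome is independent
#' of ordering) and reports per-model pass/fail with metrics.
#'
#' @param models list of `kinetic_model`.
#' @param data fermentation curves (see [screen_fermentation_fit()]), or
#'   `NULL` to replace that criterion with [screen_concentration_robustness()].
#' @param config a [bioreactor_config()].
#' @param tau_max hours; `NULL` for doubling_time/5.
#' @param cv,n_enz,growth_floor enzyme-robustness settings.
#' @param seed RNG seed.
#' @return list with `report` (data.frame) and `retained` (model indices
#'   passing all criteria).
#' @export
screen_ensemble <- function(models, data, config, tau_max = NULL,
                            cv = 0.10, n_enz = 10, growth_floor = 0.5,
                            seed = 1) {
  lin <- screen_linear_dynamics(models, tau_max)
  rows <- lapply(seq_along(models), function(i) {
    r <- lin$summary[i, ]
    ferm <- NA; enz <- NA
    if (r$pass) {
      ferm <- if (!is.null(data))
        isTRUE(screen_fermentation_fit(models[[i]], data, config))
      else screen_concentration_robustness(models[[i]], seed = seed)
      if (ferm) enz <- screen_enzyme_robustness(models[[i]], config, cv = cv,
                                                n = n_enz,
                                                growth_floor = growth_floor,
                                                seed = seed)
    }
    data.frame(model = i, stable = r$stable, tau_d = r$tau_d,
               linear_dynamics = r$pass,
               fermentation_fit = ferm, enzyme_robustness = enz,
               pass = isTRUE(r$pass) && isTRUE(ferm) && isTRUE(enz))
  })
  report <- do.call(rbind, rows)
  list(report = report, retained = report$model[report$pass])
}
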