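#' Thermodynamic data container
#'
#' @param dG0 named numeric: standard transformed Gibbs energy of reaction
#'   (kcal/mol) for every thermodynamically constrained reaction. Reactions
#'   absent from `dG0` (typically exchanges and the biomass lump) carry no
#'   Gibbs-energy variable.
#' @param conc_bounds two-column matrix (`lo`, `hi`, mol/L) with metabolite
#'   ids as row names; both bounds must be strictly positive.
#' @param RT gas constant times temperature, kcal/mol (default 298.15 K).
#' @param displacement_floor named numeric of per-reaction minimum absolute
#'   Gibbs energies |dG'| (kcal/mol); see [apply_displacement_floor()].
#' @return a `thermo_data` object.
#' @export
thermo_data <- function(dG0, conc_bounds, RT = 0.5925,
                        displacement_floor = numeric(0)) {
  stopifnot(RT > 0)
  if (any(conc_bounds[, 1] <= 0) || any(conc_bounds[, 2] < conc_bounds[, 1]))
    stop("concentration bounds must satisfy 0 < lo <= hi")
  structure(list(dG0 = dG0, conc_bounds = conc_bounds, RT = RT,
                 displacement_floor = displacement_floor),
            class = "thermo_data")
}

# Build the TFA MILP:
#   variables [v | ln x | dG' | z]
#   N_int v = 0
#   dG'_j = dG0_j + RT * sum_i n_ij ln x_i
#   z_j = 1 (forward): 0 <= v_j <= ub_j,  dG'_j <= -eps_j
#   z_j = 0 (reverse): lb_j <= v_j <= 0,  dG'_j >= +eps_j
# Direction coupling uses per-reaction big-M values derived from the flux
# bounds (x 1.1) and the attainable Gibbs-energy range.
build_tfa_lp <- function(net, thermo, flux_bounds, min_displacement = 1e-3,
                         growth_min = NULL) {
  rx <- net$reactions
  nr <- nrow(rx)
  mets <- net$metabolites$id
  nm <- length(mets)
  trx <- intersect(rx$id, names(thermo$dG0))
  nt <- length(trx)
  cb <- thermo$conc_bounds[mets, , drop = FALSE]
  lnlo <- log(cb[, 1]); lnhi <- log(cb[, 2])

  eps <- stats::setNames(rep(min_displacement, nt), trx)
  fl <- thermo$displacement_floor
  if (length(fl)) eps[intersect(names(fl), trx)] <- pmax(
    eps[intersect(names(fl), trx)], fl[intersect(names(fl), trx)])

  # attainable |dG'| range per reaction -> big-M for the sign coupling
  gmax <- vapply(trx, function(rid) {
    s <- net$stoichiometry[[rid]]
    span <- sum(abs(s) * (lnhi[names(s)] - lnlo[names(s)]))
    abs(thermo$dG0[[rid]]) + thermo$RT * span + 1
  }, 0)

  nv <- nr + nm + nt + nt
  vn <- c(paste0("v_", rx$id), paste0("lnx_", mets),
          paste0("g_", trx), paste0("z_", trx))
  iv <- stats::setNames(seq_len(nr), rx$id)
  ix <- stats::setNames(nr + seq_len(nm), mets)
  ig <- stats::setNames(nr + nm + seq_len(nt), trx)
  iz <- stats::setNames(nr + nm + nt + seq_len(nt), trx)

  lb <- c(flux_bounds[rx$id, "lb"], lnlo, -gmax - eps, rep(0, nt))
  ub <- c(flux_bounds[rx$id, "ub"], lnhi, gmax + eps, rep(1, nt))
  vtype <- c(rep("C", nr + nm + nt), rep("B", nt))

  rows <- list(); sense <- character(0); rhs <- numeric(0)
  add <- function(r, s, b) {
    rows[[length(rows) + 1L]] <<- r; sense <<- c(sense, s); rhs <<- c(rhs, b)
  }
  # internal species are balanced; boundary species are balanced too when an
  # exchange pseudo-reaction supplies/drains them (the system boundary) --
  # otherwise their pools are external reservoirs outside the steady-state
  # balance (e.g. a finite batch medium)
  N_all <- stoichiometric_matrix(net, "all")
  exch <- rx$id[rx$is_exchange]
  bnd <- boundary_met_ids(net)
  balanced <- union(setdiff(rownames(N_all), bnd),
                    bnd[rowSums(abs(N_all[bnd, exch, drop = FALSE])) > 0])
  for (i in which(rownames(N_all) %in% balanced)) {
    r <- numeric(nv); r[iv] <- N_all[i, ]
    add(r, "=", 0)
  }
  vbig <- 1.1  # big-M inflation on flux bounds for the direction coupling
  for (rid in trx) {
    s <- net$stoichiometry[[rid]]
    r <- numeric(nv)
    r[ig[[rid]]] <- 1
    r[ix[names(s)]] <- -thermo$RT * s
    add(r, "=", thermo$dG0[[rid]])
    lbj <- flux_bounds[rid, "lb"]; ubj <- flux_bounds[rid, "ub"]
    # v_j <= ub_j * z_j
    r <- numeric(nv); r[iv[[rid]]] <- 1; r[iz[[rid]]] <- -max(ubj, 0) * vbig
    add(r, "<=", 0)
    # v_j >= lb_j * (1 - z_j)
    r <- numeric(nv); r[iv[[rid]]] <- 1; r[iz[[rid]]] <- min(lbj, 0) * vbig
    add(r, ">=", min(lbj, 0) * vbig)
    # dG'_j <= -eps_j + Mg (1 - z_j)
    Mg <- gmax[[rid]] + eps[[rid]]
    r <- numeric(nv); r[ig[[rid]]] <- 1; r[iz[[rid]]] <- Mg
    add(r, "<=", Mg - eps[[rid]])
    # dG'_j >= eps_j - Mg z_j
    r <- numeric(nv); r[ig[[rid]]] <- 1; r[iz[[rid]]] <- Mg
    add(r, ">=", eps[[rid]])
    if (lbj > 0) lb[iz[[rid]]] <- 1    # strictly positive flux: direction fixed
    if (ubj < 0) ub[iz[[rid]]] <- 0
  }
  if (!is.null(growth_min)) {
    r <- numeric(nv); r[iv[[net$biomass_reaction]]] <- 1
    add(r, ">=", growth_min)
  }
  obj <- numeric(nv); obj[iv[[net$biomass_reaction]]] <- 1
  prob <- lp_problem(obj, A = do.call(rbind, rows), sense = sense, rhs = rhs,
                     lb = lb, ub = ub, vtype = vtype, maximize = TRUE,
                     names = vn)
  prob$tfa <- list(iv = iv, ix = ix, ig = ig, iz = iz, trx = trx, eps = eps,
                   net = net, thermo = thermo)
  prob
}

#' Maximal thermodynamically feasible growth
#'
#' Maximizes the biomass flux subject to internal mass balance, flux and
#' concentration bounds, and the second-law coupling that forces every
#' carried flux to run downhill in Gibbs energy (big-M direction binaries).
#'
#' @param net a `metabolic_network`.
#' @param thermo a `thermo_data`.
#' @param flux_bounds two-column (`lb`, `ub`) matrix with reaction row names.
#' @param min_displacement minimum |dG'| (kcal/mol) enforced for reactions
#'   carrying flux; keeps the second law strict rather than marginal.
#' @return maximal growth rate (units of the biomass flux, 1/h by the
#'   package's fixture convention).
#' @export
max_growth <- function(net, thermo, flux_bounds, min_displacement = 1e-3) {
  prob <- build_tfa_lp(net, thermo, flux_bounds, min_displacement)
  res <- milp_solve(prob)
  if (res$status != "optimal")
    stop("TFA problem infeasible: check flux bounds, concentration bounds, ",
         "and displacement floors (binding constraint groups: mass balance, ",
         "Gibbs-energy coupling)")
  res$objval
}

#' Enforce a minimum thermodynamic displacement for one reaction
#'
#' Forces `|dG'| >= floor` (kcal/mol) for the named reaction in all
#' subsequently drawn samples, displacing it away from equilibrium.
#'
#' @param thermo a `thermo_data`.
#' @param reaction reaction id.
#' @param floor minimum |dG'| in kcal/mol (e.g. 1.25).
#' @return modified `thermo_data`.
#' @export
apply_displacement_floor <- function(thermo, reaction, floor) {
  stopifnot(floor >= 0)
  if (!reaction %in% names(thermo$dG0))
    stop("reaction '", reaction, "' has no Gibbs-energy variable")
  thermo$displacement_floor[reaction] <- floor
  thermo
}

#' Attainable Gibbs-energy range of a reaction
#'
#' Minimum and maximum of `dG'` over the TFA-feasible space (with direction
#' coupling relaxed for the queried reaction), computed by two MILPs. Used to
#' check whether a displacement floor is attainable.
#'
#' @inheritParams max_growth
#' @param reaction reaction id.
#' @return numeric `c(lo, hi)`.
#' @export
dG_range <- function(net, thermo, flux_bounds, reaction,
                     min_displacement = 1e-3) {
  out <- c(NA_real_, NA_real_)
  for (k in 1:2) {
    prob <- build_tfa_lp(net, thermo, flux_bounds, min_displacement)
    prob$obj[] <- 0
    prob$obj[prob$tfa$ig[[reaction]]] <- 1
    prob$maximize <- (k == 2)
    res <- milp_solve(prob)
    if (res$status != "optimal") stop("TFA problem infeasible")
    out[k] <- res$objval
  }
  stats::setNames(out, c("lo", "hi"))
}

profile_from_solution <- function(prob, x) {
  tfa <- prob$tfa
  net <- tfa$net
  fluxes <- stats::setNames(x[tfa$iv], names(tfa$iv))
  ln_conc <- stats::setNames(x[tfa$ix], names(tfa$ix))
  dG <- stats::setNames(rep(NA_real_, length(fluxes)), names(fluxes))
  dG[tfa$trx] <- x[tfa$ig]
  structure(list(fluxes = fluxes, ln_conc = ln_conc, dG = dG,
                 growth_rate = unname(fluxes[net$biomass_reaction])),
            class = "steady_state_profile")
}

#' @export
print.steady_state_profile <- function(x, ...) {
  cat("Steady-state profile: growth", signif(x$growth_rate, 4),
      "| ", length(x$fluxes), "fluxes,", length(x$ln_conc), "species\n")
  invisible(x)
}

#' Sample thermodynamically consistent steady states
#'
#' Draws vertex samples of the TFA-feasible space at near-maximal growth by
#' optimizing random objective directions over the flux and log-concentration
#' variables ("optimize a random direction, record the vertex"). Every sample
#' satisfies mass balance, bounds, `dG' = dG'0 + RT * sum n ln x`, and the
#' second law `sign(v) * dG' < 0` for every reaction that carries flux.
#'
#' @inheritParams max_growth
#' @param n number of samples.
#' @param growth_fraction samples must achieve at least this fraction of the
#'   maximal growth (default 0.8).
#' @param seed RNG seed; the sample list is reproducible under a fixed seed.
#' @return list of `steady_state_profile` objects.
#' @export
sample_steady_states <- function(net, thermo, flux_bounds, n,
                                 growth_fraction = 0.8, seed = 1,
                                 min_displacement = 1e-3) {
  mu_max <- max_growth(net, thermo, flux_bounds, min_displacement)
  if (mu_max <= 0) stop("maximal growth is zero; nothing to sample")
  prob <- build_tfa_lp(net, thermo, flux_bounds, min_displacement,
                       growth_min = growth_fraction * mu_max)
  nv <- length(prob$obj)
  nr <- length(prob$tfa$iv); nm <- length(prob$tfa$ix)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- vector("list", n)
  n_fail <- 0L
  for (k in seq_len(n)) {
    dirn <- stats::rnorm(nr + nm)
    prob$obj[] <- 0
    prob$obj[seq_len(nr + nm)] <- dirn
    res <- milp_solve(prob)
    if (res$status != "optimal") {
      n_fail <- n_fail + 1L
      next
    }
    out[[k]] <- profile_from_solution(prob, res$x)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (n_fail > 0L)
    warning(n_fail, " of ", n, " sampling LPs failed; returning ",
            length(out), " profiles")
  out
}

#' Check the invariants of a steady-state profile
#'
#' Verifies internal mass balance, concentration bounds, the Gibbs-energy
#' identity and the second law; used by tests and by the kinetic sampler as
#' a precondition.
#'
#' @param profile a `steady_state_profile`.
#' @param net,thermo as elsewhere.
#' @param tol tolerances for balance and the Gibbs identity.
#' @return TRUE (invisibly) or an error describing the violated invariant.
#' @export
validate_profile <- function(profile, net, thermo, tol = 1e-8) {
  N <- stoichiometric_matrix(net, "internal")
  res <- max(abs(N %*% profile$fluxes[colnames(N)]))
  if (res > tol) stop("mass-balance residual ", res)
  cb <- thermo$conc_bounds[names(profile$ln_conc), , drop = FALSE]
  x <- exp(profile$ln_conc)
  if (any(x < cb[, 1] * (1 - 1e-9) | x > cb[, 2] * (1 + 1e-9)))
    stop("concentration outside bounds")
  for (rid in intersect(names(thermo$dG0), names(profile$fluxes))) {
    s <- net$stoichiometry[[rid]]
    g <- thermo$dG0[[rid]] + thermo$RT * sum(s * profile$ln_conc[names(s)])
    if (abs(g - profile$dG[[rid]]) > tol)
      stop("Gibbs identity violated for ", rid)
    v <- profile$fluxes[[rid]]
    if (abs(v) > 1e-9 && !(sign(v) * profile$dG[[rid]] < 0))
      stop("second law violated for ", rid)
  }
  invisible(TRUE)
}

#' Serialize steady-state profiles to CSV
#'
#' One row per (profile, kind, id): reactions carry flux, dG'0 and dG';
#' metabolites carry the log-concentration.
#' @param profiles list of `steady_state_profile`.
#' @param thermo a `thermo_data` (for dG'0 values).
#' @param path output CSV path.
#' @export
write_profiles_csv <- function(profiles, thermo, path) {
  rows <- list()
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    rows[[length(rows) + 1L]] <- data.frame(
      profile = k, kind = "reaction", id = names(p$fluxes),
      value = unname(p$fluxes),
      dG0 = unname(thermo$dG0[names(p$fluxes)]),
      dG = unname(p$dG), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      profile = k, kind = "metabolite", id = names(p$ln_conc),
      value = unname(p$ln_conc), dG0 = NA_real_, dG = NA_real_,
      stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
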