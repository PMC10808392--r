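#' Designable enzymes of a network
#'
#' Enzymatic targets for intervention design: every reaction except exchange
#' pseudo-reactions, the biomass lump, and periplasm-to-extracellular
#' transports (modeled as non-enzymatic mass action).
#' @param net a `metabolic_network`.
#' @return character vector of reaction ids.
#' @export
designable_enzymes <- function(net) {
  laws <- assign_rate_laws(net)
  keep <- !net$reactions$is_exchange &
    net$reactions$id != net$biomass_reaction &
    !(net$reactions$is_transport & laws$law == "mass_action")
  net$reactions$id[keep]
}

#' Build a network-response-analysis design problem
#'
#' Casts strain design as a MILP over the control coefficients: continuous
#' log activity changes `u_j >= 0` (up) and `d_j >= 0` (down) per designable
#' enzyme with direction binaries, log-linear responses
#' `dln x_i = sum_j C_x[i,j] (u_j - d_j)` bounded by the allowed fold change
#' in concentrations, a cap on the growth-rate reduction, a cap on the
#' number of interventions, and the objective of maximizing the product
#' yield with respect to substrate uptake,
#' `max sum_j (C_v[product,j] - C_v[uptake,j]) (u_j - d_j)`.
#'
#' @param cc a `control_coefficients`.
#' @param net the `metabolic_network` (for the designable-enzyme set).
#' @param conc_fold maximum fold change of any internal concentration
#'   (default 3).
#' @param up_fold maximum enzyme-activity upregulation (default 5).
#' @param down_fold maximum downregulation; "unrestricted" downregulation is
#'   encoded as a finite 100-fold cap (a MILP needs a finite big-M).
#' @param max_interventions maximum number of targeted enzymes (default 3).
#' @param growth_drop_max maximum relative growth-rate reduction (default
#'   0.2).
#' @param flux_fold optional maximum fold change of any flux (off by
#'   default; the phenotype proximity bounds used in practice act on
#'   concentrations and growth).
#' @param designable optional explicit enzyme set.
#' @param epsilon_membership minimum log activity change implied by a set
#'   direction binary (default 1e-6), tying binaries to real interventions.
#' @return an `nra_problem` wrapping an [lp_problem()] plus index maps.
#' @export
build_nra_problem <- function(cc, net, conc_fold = 3, up_fold = 5,
                              down_fold = 100, max_interventions = 3,
                              growth_drop_max = 0.2, flux_fold = NULL,
                              designable = NULL, epsilon_membership = 1e-6) {
  stopifnot(conc_fold > 1, up_fold > 1, down_fold > 1, max_interventions >= 0)
  enz <- if (is.null(designable)) designable_enzymes(net) else designable
  enz <- intersect(colnames(cc$C_v), enz)
  nd <- length(enz)
  # variables: u (nd) | d (nd) | bu (nd) | bd (nd)
  iu <- seq_len(nd); id_ <- nd + iu; ibu <- 2 * nd + iu; ibd <- 3 * nd + iu
  nv <- 4 * nd
  lb <- rep(0, nv)
  ub <- c(rep(log(up_fold), nd), rep(log(down_fold), nd), rep(1, 2 * nd))
  vtype <- c(rep("C", 2 * nd), rep("B", 2 * nd))
  rows <- list(); sense <- character(0); rhs <- numeric(0)
  add <- function(r, s, b) {
    rows[[length(rows) + 1L]] <<- r; sense <<- c(sense, s); rhs <<- c(rhs, b)
  }
  for (j in seq_len(nd)) {
    r <- numeric(nv); r[iu[j]] <- 1; r[ibu[j]] <- -log(up_fold)
    add(r, "<=", 0)
    r <- numeric(nv); r[id_[j]] <- 1; r[ibd[j]] <- -log(down_fold)
    add(r, "<=", 0)
    # a set direction binary implies a real (>= epsilon) activity change, so
    # binaries and active supports coincide and integer cuts are airtight
    r <- numeric(nv); r[iu[j]] <- 1; r[ibu[j]] <- -epsilon_membership
    add(r, ">=", 0)
    r <- numeric(nv); r[id_[j]] <- 1; r[ibd[j]] <- -epsilon_membership
    add(r, ">=", 0)
    r <- numeric(nv); r[ibu[j]] <- 1; r[ibd[j]] <- 1
    add(r, "<=", 1)
  }
  r <- numeric(nv); r[c(ibu, ibd)] <- 1
  add(r, "<=", max_interventions)
  # concentration proximity
  Cx <- cc$C_x[, enz, drop = FALSE]
  for (i in seq_len(nrow(Cx))) {
    r <- numeric(nv); r[iu] <- Cx[i, ]; r[id_] <- -Cx[i, ]
    add(r, "<=", log(conc_fold))
    add(-r, "<=", log(conc_fold))
  }
  # optional flux proximity
  if (!is.null(flux_fold)) {
    Cv <- cc$C_v[, enz, drop = FALSE]
    for (i in seq_len(nrow(Cv))) {
      r <- numeric(nv); r[iu] <- Cv[i, ]; r[id_] <- -Cv[i, ]
      add(r, "<=", log(flux_fold))
      add(-r, "<=", log(flux_fold))
    }
  }
  # growth protection
  g <- cc$C_v[cc$biomass, enz]
  r <- numeric(nv); r[iu] <- g; r[id_] <- -g
  add(r, ">=", log(1 - growth_drop_max))
  obj <- numeric(nv)
  yld <- cc$C_yield[enz]
  obj[iu] <- yld; obj[id_] <- -yld
  prob <- lp_problem(obj, A = do.call(rbind, rows), sense = sense, rhs = rhs,
                     lb = lb, ub = ub, vtype = vtype, maximize = TRUE,
                     names = c(paste0("u_", enz), paste0("d_", enz),
                               paste0("bu_", enz), paste0("bd_", enz)))
  structure(list(lp = prob, enzymes = enz, iu = iu, id = id_, ibu = ibu,
                 ibd = ibd, cc = cc,
                 bounds = list(conc_fold = conc_fold, up_fold = up_fold,
                               down_fold = down_fold,
                               max_interventions = max_interventions,
                               growth_drop_max = growth_drop_max,
                               flux_fold = flux_fold)),
            class = "nra_problem")
}

design_from_solution <- function(problem, res, active_tol = 1e-7) {
  x <- res$x
  up <- which(round(x[problem$ibu]) == 1 & x[problem$iu] > active_tol)
  dn <- which(round(x[problem$ibd]) == 1 & x[problem$id] > active_tol)
  design <- rbind(
    data.frame(enzyme = problem$enzymes[up],
               direction = rep("up", length(up)),
               fold = exp(x[problem$iu][up]), stringsAsFactors = FALSE),
    data.frame(enzyme = problem$enzymes[dn],
               direction = rep("down", length(dn)),
               fold = exp(x[problem$id][dn]), stringsAsFactors = FALSE))
  design <- design[order(design$enzyme), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(interventions = design,
                 predicted_objective = res$objval,
                 yield_gain_percent = 100 * (exp(res$objval) - 1)),
            class = "intervention_design")
}

#' @export
print.intervention_design <- function(x, ...) {
  cat("Intervention design: ",
      if (nrow(x$interventions) == 0) "(none)" else
        paste(sprintf("%s%s x%.2f", x$interventions$enzyme,
                      ifelse(x$interventions$direction == "up", "+", "-"),
                      x$interventions$fold), collapse = ", "),
      "\n  predicted yield gain: ", sprintf("%.1f%%", x$yield_gain_percent),
      " (log objective ", signif(x$predicted_objective, 4), ")\n", sep = "")
  invisible(x)
}

#' Solve an NRA design problem to optimality
#'
#' @param problem an `nra_problem`.
#' @return an `intervention_design` with the active enzymes read off the
#'   direction binaries; the objective is reported both in log space and as
#'   a percent yield increase.
#' @export
solve_nra <- function(problem) {
  res <- milp_solve(problem$lp)
  if (res$status != "optimal")
    stop("NRA problem ", res$status,
         " (check growth-drop and concentration-fold constraints)")
  design_from_solution(problem, res)
}

signed_support <- function(design) {
  iv <- design$interventions
  if (nrow(iv) == 0) return(character(0))
  sort(paste0(iv$enzyme, ifelse(iv$direction == "up", "+", "-")))
}

# integer cut excluding exactly this signed support
add_support_cut <- function(problem, support) {
  nv <- length(problem$lp$obj)
  r <- numeric(nv)
  lab <- c(paste0(problem$enzymes, "+"), paste0(problem$enzymes, "-"))
  bidx <- c(problem$ibu, problem$ibd)
  inset <- lab %in% support
  r[bidx[inset]] <- 1
  r[bidx[!inset]] <- -1
  problem$lp <- lp_add_rows(problem$lp, r, "<=", length(support) - 1)
  problem
}

#' Enumerate near-optimal alternative designs
#'
#' Iteratively re-solves the MILP with integer cuts that exclude each found
#' signed support (enzyme-and-direction set), collecting every design whose
#' objective is within `tolerance` of the optimum. Designs differing only in
#' fold-change magnitude are represented once by their support.
#'
#' @param problem an `nra_problem`.
#' @param tolerance relative objective tolerance (default 0.05).
#' @param max_designs cap on the number of designs returned.
#' @return a `design_enumeration`: list of `intervention_design`, the
#'   optimum, the tolerance, and the unique membership list.
#' @export
enumerate_designs <- function(problem, tolerance = 0.05, max_designs = 100) {
  first <- solve_nra(problem)
  optimum <- first$predicted_objective
  designs <- list(first)
  if (length(signed_support(first)) > 0 && optimum > 0) {
    p <- add_support_cut(problem, signed_support(first))
    while (length(designs) < max_designs) {
      res <- milp_solve(p$lp)
      if (res$status != "optimal") break
      if (res$objval < (1 - tolerance) * optimum - 1e-9) break
      d <- design_from_solution(p, res)
      if (length(signed_support(d)) == 0) break
      designs[[length(designs) + 1L]] <- d
      p <- add_support_cut(p, signed_support(d))
    }
  }
  # post-hoc constraint audit: every enumerated design must satisfy the
  # original problem when its support is enforced (no cut leakage)
  for (d in designs) {
    chk <- evaluate_design_across_models(signed_support(d), list(problem))
    if (!is.finite(chk$objectives[1]) ||
        chk$objectives[1] < d$predicted_objective - 1e-6)
      stop("enumerated design fails re-check: ",
           paste(signed_support(d), collapse = ","))
  }
  structure(list(designs = designs, optimum = optimum, tolerance = tolerance,
                 memberships = unique(lapply(designs, signed_support))),
            class = "design_enumeration")
}

#' @export
print.design_enumeration <- function(x, ...) {
  cat("Design enumeration:", length(x$designs), "designs within",
      sprintf("%.0f%%", 100 * x$tolerance), "of the optimum",
      signif(x$optimum, 4), "\n")
  invisible(x)
}

#' Evaluate a fixed design membership across models
#'
#' For each model's NRA problem, restricts the interventions to the given
#' signed support (non-members fixed to zero; members required to move by at
#' least `epsilon` in log activity) and maximizes the objective. Models for
#' which the support is infeasible score `-Inf` and are excluded from the
#' mean (flagged).
#'
#' @param membership character vector of signed support labels, e.g.
#'   `c("BR1+", "BR2-")`.
#' @param problems list of `nra_problem` (one per model).
#' @param epsilon minimum log fold change for member enzymes (default 1e-6).
#' @return list with `objectives` (per model), `mean` (over feasible
#'   models), `n_infeasible`.
#' @export
evaluate_design_across_models <- function(membership, problems,
                                          epsilon = 1e-6) {
  objs <- vapply(problems, function(p) {
    lab <- c(paste0(p$enzymes, "+"), paste0(p$enzymes, "-"))
    if (!all(membership %in% lab)) return(-Inf)
    bidx <- c(p$ibu, p$ibd)
    vidx <- c(p$iu, p$id)
    inset <- lab %in% membership
    lp <- p$lp
    lp$lb[bidx[inset]] <- 1
    lp$ub[bidx[!inset]] <- 0
    lp$ub[vidx[!inset]] <- 0
    lp$lb[vidx[inset]] <- epsilon
    res <- milp_solve(lp)
    if (res$status != "optimal") return(-Inf)
    res$objval
  }, 0)
  feas <- is.finite(objs)
  list(objectives = objs, mean = mean(objs[feas]),
       n_infeasible = sum(!feas))
}

#' Rank unique designs across a model ensemble
#'
#' Deduplicates the enumerated designs by signed support, scores each
#' support by its mean cross-model NRA objective (see
#' [evaluate_design_across_models()]), and returns the top `top_k`.
#' Ties break lexicographically on the support labels, and the result is
#' invariant to the order of the models.
#'
#' @param enumerations list of `design_enumeration` (one per model).
#' @param problems list of `nra_problem` (one per model).
#' @param top_k how many designs to return (default 5).
#' @param epsilon minimum member activity change.
#' @return data.frame: support label, mean objective, mean yield gain (%),
#'   number of models where infeasible.
#' @export
rank_designs <- function(enumerations, problems, top_k = 5, epsilon = 1e-6) {
  members <- unique(unlist(lapply(enumerations, function(e)
    lapply(e$memberships, paste, collapse = ",")), use.names = FALSE))
  members <- members[nzchar(members)]
  rows <- lapply(sort(members), function(lab) {
    supp <- strsplit(lab, ",", fixed = TRUE)[[1]]
    ev <- evaluate_design_across_models(supp, problems, epsilon)
    data.frame(design = lab, mean_objective = ev$mean,
               mean_yield_gain_percent = 100 * (exp(ev$mean) - 1),
               n_infeasible = ev$n_infeasible, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_objective, out$design), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Write designs to CSV/JSON
#' @param enumeration a `design_enumeration`.
#' @param path output path; format chosen by extension (.csv or .json).
#' @export
write_designs <- function(enumeration, path) {
  tab <- do.call(rbind, lapply(seq_along(enumeration$designs), function(i) {
    d <- enumeration$designs[[i]]
    if (nrow(d$interventions) == 0) return(NULL)
    cbind(design = i, d$interventions,
          predicted_objective = d$predicted_objective,
          yield_gain_percent = d$yield_gain_percent)
  }))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
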