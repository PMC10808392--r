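#' Log-linear elasticities at the anchor state
#'
#' Analytic scaled derivatives `d ln v / d ln x` of every rate law with
#' respect to the internal species, evaluated at the anchor, plus the
#' enzyme-elasticity matrix `Pi` (identity under the one-enzyme-per-reaction
#' convention, since all laws are proportional to their maximal rate).
#'
#' Reactions close to equilibrium have large but finite elasticities (the
#' `1 - Gamma` factor); they are reported, not errored, and
#' [near_equilibrium_report()] lists them.
#'
#' @param model a `kinetic_model`.
#' @return list with `E_x` (reactions x internal species) and `Pi`
#'   (reactions x enzymes).
#' @export
elasticity_matrix <- function(model) {
  re <- rate_and_elasticity(model, model$anchor$ln_conc)
  int <- internal_met_ids(model$net)
  E_x <- re$E[, int, drop = FALSE]
  n <- nrow(E_x)
  Pi <- diag(n)
  dimnames(Pi) <- list(rownames(E_x), rownames(E_x))
  list(E_x = E_x, Pi = Pi)
}

#' Reactions operating near thermodynamic equilibrium
#'
#' Enzymes whose reactions sit close to equilibrium exert little flux
#' control no matter how much their activity changes; this diagnostic lists
#' reactions with `|dG'|` below a threshold at the anchor.
#'
#' @param model a `kinetic_model`.
#' @param threshold kcal/mol (default 0.5).
#' @param RT gas constant times temperature, kcal/mol.
#' @return data.frame of reaction, dG' and the displacement `exp(dG'/RT)`.
#' @export
near_equilibrium_report <- function(model, threshold = 0.5, RT = 0.5925) {
  dG <- model$anchor$dG
  sel <- !is.na(dG) & abs(dG) < threshold
  data.frame(reaction = names(dG)[sel], dG = unname(dG[sel]),
             displacement = exp(unname(dG[sel]) / RT))
}

#' Flux and concentration control coefficients
#'
#' Solves the log-linear steady-state response of the network to enzyme
#' activity changes:
#' `C_x = -(N_R V E_x L_s)^{-1} N_R V Pi` and `C_v = E_x L_s C_x + Pi`,
#' with `V = diag(anchor fluxes)`, `L_s` the concentration-scaled link
#' matrix restricting to independent species, and `Pi = I`. The flux rows
#' sum to 1 and the concentration rows to 0 (summation theorems), which is
#' verified at construction.
#'
#' @param model a stable, anchored `kinetic_model`.
#' @param check_tol tolerance for the summation-theorem check (1e-8).
#' @return a `control_coefficients` object: `C_v` (reactions x enzymes),
#'   `C_x` (internal species x enzymes), `C_yield` (named vector,
#'   `C_v[product,] - C_v[uptake,]`), plus the network roles.
#' @export
control_coefficients <- function(model, check_tol = 1e-8) {
  net <- model$net
  em <- elasticity_matrix(model)
  lm <- link_matrix(net)
  int <- rownames(lm$L)
  x <- exp(model$anchor$ln_conc)
  # scaled link: d ln x_all = Ls d ln x_indep around the anchor
  Ls <- diag(1 / x[int], nrow = length(int)) %*% lm$L %*%
    diag(x[lm$indep], nrow = length(lm$indep))
  dimnames(Ls) <- dimnames(lm$L)
  V <- diag(model$anchor$fluxes[colnames(lm$NR)],
            nrow = ncol(lm$NR))
  M <- lm$NR %*% V %*% em$E_x[colnames(lm$NR), int, drop = FALSE] %*% Ls
  rhs <- lm$NR %*% V %*% em$Pi
  Cxi <- tryCatch(-solve(M, rhs), error = function(e)
    stop("singular control system; model unusable for design"))
  Cx <- Ls %*% Cxi                      # all internal species
  Cv <- em$E_x[, int, drop = FALSE] %*% Cx + em$Pi
  rownames(Cx) <- int
  colnames(Cx) <- colnames(Cv) <- colnames(em$Pi)
  fsum <- max(abs(rowSums(Cv) - 1))
  csum <- max(abs(rowSums(Cx)))
  if (fsum > check_tol || csum > check_tol)
    stop("summation theorems violated (flux ", signif(fsum, 3),
         ", concentration ", signif(csum, 3), ")")
  prd <- product_flux_reaction(net)
  upt <- uptake_flux_reaction(net)
  yield <- Cv[prd, ] - Cv[upt, ]
  structure(list(C_v = Cv, C_x = Cx, C_yield = yield,
                 biomass = net$biomass_reaction,
                 product = prd,
                 uptake = upt),
            class = "control_coefficients")
}

#' @export
print.control_coefficients <- function(x, ...) {
  cat("Control coefficients:", nrow(x$C_v), "fluxes x", ncol(x$C_v),
      "enzymes;", nrow(x$C_x), "species\n")
  top <- sort(abs(x$C_yield), decreasing = TRUE)
  cat("  top yield control:", paste(names(top)[seq_len(min(3, length(top)))],
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Top-k enzyme targets by control coefficient
#'
#' Ranks enzymes by the absolute value of their yield (or product-flux)
#' control coefficient; the coefficient's sign gives the direction
#' (positive, upregulate). Ties break lexicographically by enzyme id.
#'
#' @param cc a `control_coefficients`.
#' @param objective `"yield"` (product minus uptake) or `"flux"` (product
#'   flux row).
#' @param k number of targets (capped at the enzyme count).
#' @return data.frame `enzyme`, `coefficient`, `direction`.
#' @export
top_k_targets <- function(cc, objective = c("yield", "flux"), k = 3) {
  objective <- match.arg(objective)
  v <- if (objective == "yield") cc$C_yield else cc$C_v[cc$product, ]
  ord <- order(-abs(v), names(v))
  ord <- ord[seq_len(min(k, length(v)))]
  data.frame(enzyme = names(v)[ord], coefficient = unname(v[ord]),
             direction = ifelse(v[ord] >= 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Write control-coefficient matrices to CSV
#' @param cc a `control_coefficients`; `path` output file.
#' @param path output CSV path.
#' @export
write_control_coefficients_csv <- function(cc, path) {
  df <- rbind(data.frame(kind = "flux", id = rownames(cc$C_v), cc$C_v,
                         check.names = FALSE),
              data.frame(kind = "concentration", id = rownames(cc$C_x),
                         cc$C_x, check.names = FALSE),
              data.frame(kind = "yield", id = "yield", t(cc$C_yield),
                         check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Exchange pseudo-reactions act on fixed boundary species, so their rate laws
# carry no control; the product (uptake) flux whose response matters is the
# last transport that produces (first that consumes) the boundary species.
product_flux_reaction <- function(net) {
  rid <- net$objective_product
  if (!net$reactions$is_exchange[net$reactions$id == rid]) return(rid)
  sp <- intersect(names(net$stoichiometry[[rid]]), boundary_met_ids(net))[1]
  feeders <- net$reactions$id[vapply(net$reactions$id, function(r) {
    s <- net$stoichiometry[[r]]
    !net$reactions$is_exchange[net$reactions$id == r] &&
      sp %in% names(s) && s[[sp]] > 0
  }, TRUE)]
  if (length(feeders) == 0) rid else feeders[1]
}

uptake_flux_reaction <- function(net) {
  rid <- net$substrate_uptake
  if (!net$reactions$is_exchange[net$reactions$id == rid]) return(rid)
  sp <- intersect(names(net$stoichiometry[[rid]]), boundary_met_ids(net))[1]
  takers <- net$reactions$id[vapply(net$reactions$id, function(r) {
    s <- net$stoichiometry[[r]]
    !net$reactions$is_exchange[net$reactions$id == r] &&
      sp %in% names(s) && s[[sp]] < 0
  }, TRUE)]
  if (length(takers) == 0) rid else takers[1]
}
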