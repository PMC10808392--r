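#' Construct a metabolic network
#'
#' A `metabolic_network` bundles the stoichiometry, compartment structure and
#' regulatory annotations of a metabolic model, together with the identities
#' of the three reactions every design study needs: the biomass lump, the
#' product exchange being optimized, and the substrate uptake.
#'
#' Boundary metabolites (`is_boundary = TRUE`) are species whose
#' concentration is held fixed in intracellular dynamics; they become dynamic
#' only when a batch bioreactor is wrapped around the network (see
#' [simulate_batch()]).
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `is_boundary`.
#' @param reactions data.frame with columns `id`, `reversible`,
#'   `is_transport`, `is_exchange` and optionally `gene_label`.
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   (by metabolite id); negative coefficients are substrates. Zero
#'   coefficients are dropped.
#' @param regulations data.frame with columns `regulator` (metabolite id),
#'   `target` (reaction id), `mode` (one of `"competitive_inhibition"`,
#'   `"uncompetitive_inhibition"`, `"mixed_inhibition"`, `"activation"`).
#' @param compartments character vector of declared compartment ids.
#' @param biomass_reaction,objective_product,substrate_uptake reaction ids.
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry,
                              regulations = NULL, compartments = NULL,
                              biomass_reaction, objective_product,
                              substrate_uptake) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$gene_label)) reactions$gene_label <- NA_character_
  if (is.null(regulations))
    regulations <- data.frame(regulator = character(), target = character(),
                              mode = character(), stringsAsFactors = FALSE)
  if (is.null(compartments)) compartments <- unique(metabolites$compartment)
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite id(s): ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction id(s)")
  if (!all(metabolites$compartment %in% compartments))
    stop("metabolite compartment not in declared compartment set")
  stoichiometry <- lapply(stoichiometry, function(s) s[s != 0])
  if (!setequal(names(stoichiometry), reactions$id))
    stop("stoichiometry list must be named by the reaction ids")
  stoichiometry <- stoichiometry[reactions$id]
  for (rid in reactions$id) {
    s <- stoichiometry[[rid]]
    if (length(s) == 0L) stop("reaction ", rid, " has empty stoichiometry")
    bad <- setdiff(names(s), metabolites$id)
    if (length(bad))
      stop("reaction ", rid, " references undeclared metabolite(s): ",
           paste(bad, collapse = ", "))
  }
  modes <- c("competitive_inhibition", "uncompetitive_inhibition",
             "mixed_inhibition", "activation")
  if (nrow(regulations)) {
    if (!all(regulations$mode %in% modes))
      stop("unknown regulation mode(s): ",
           paste(setdiff(regulations$mode, modes), collapse = ", "))
    if (!all(regulations$regulator %in% metabolites$id))
      stop("regulation regulator not a declared metabolite")
    if (!all(regulations$target %in% reactions$id))
      stop("regulation target not a declared reaction")
  }
  for (rid in c(biomass_reaction, objective_product, substrate_uptake))
    if (!rid %in% reactions$id)
      stop("special reaction '", rid, "' not in the network")
  structure(list(metabolites = metabolites, reactions = reactions,
                 stoichiometry = stoichiometry, regulations = regulations,
                 compartments = compartments,
                 biomass_reaction = biomass_reaction,
                 objective_product = objective_product,
                 substrate_uptake = substrate_uptake),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network:", nrow(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites,",
      length(x$compartments), "compartment(s),",
      nrow(x$regulations), "regulatory interaction(s)\n")
  cat("  biomass:", x$biomass_reaction,
      " product:", x$objective_product,
      " uptake:", x$substrate_uptake, "\n")
  invisible(x)
}

#' Stoichiometric matrix
#'
#' @param net a `metabolic_network`.
#' @param scope `"all"` keeps every metabolite row; `"internal"` drops
#'   boundary (fixed-concentration) metabolites.
#' @return numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoichiometric_matrix <- function(net, scope = c("all", "internal")) {
  scope <- match.arg(scope)
  mets <- net$metabolites$id
  if (scope == "internal") mets <- mets[!net$metabolites$is_boundary]
  N <- matrix(0, length(mets), nrow(net$reactions),
              dimnames = list(mets, net$reactions$id))
  for (rid in net$reactions$id) {
    s <- net$stoichiometry[[rid]]
    keep <- names(s) %in% mets
    if (any(keep)) N[names(s)[keep], rid] <- s[keep]
  }
  N
}

# Row-reduced echelon form with a zero tolerance; returns the reduced matrix
# and the pivot column indices. Used for conservation analysis so that test
# bases are reproducible.
rref_tol <- function(A, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  piv <- integer(0)
  r <- 1L
  for (j in seq_len(n)) {
    if (r > m) break
    i <- which.max(abs(A[r:m, j])) + r - 1L
    if (abs(A[i, j]) <= tol) next
    if (i != r) A[c(i, r), ] <- A[c(r, i), ]
    A[r, ] <- A[r, ] / A[r, j]
    for (k in seq_len(m)) {
      if (k != r && abs(A[k, j]) > tol) A[k, ] <- A[k, ] - A[k, j] * A[r, ]
    }
    piv <- c(piv, j)
    r <- r + 1L
  }
  A[abs(A) < tol] <- 0
  list(R = A, pivots = piv)
}

#' Conservation relations (conserved moieties)
#'
#' Computes a basis of the left null space of the internal stoichiometric
#' matrix by row-reduced elimination with a `1e-9` zero tolerance. Each
#' returned vector `l` satisfies `t(l) %*% N = 0`; the weighted metabolite sum
#' `sum(l * x)` is invariant under any flux distribution.
#'
#' @param net a `metabolic_network`.
#' @return a matrix whose rows are conservation vectors (possibly 0 rows),
#'   with internal metabolite ids as column names.
#' @export
conservation_relations <- function(net) {
  N <- stoichiometric_matrix(net, "internal")
  if (nrow(N) == 0L) return(matrix(0, 0, 0))
  # left null space of N = null space of t(N)
  rr <- rref_tol(t(N))
  piv <- rr$pivots
  free <- setdiff(seq_len(nrow(N)), piv)
  if (length(free) == 0L)
    return(matrix(0, 0, nrow(N), dimnames = list(NULL, rownames(N))))
  B <- matrix(0, length(free), nrow(N), dimnames = list(NULL, rownames(N)))
  for (k in seq_along(free)) {
    f <- free[k]
    v <- numeric(nrow(N))
    v[f] <- 1
    # pivot rows r of rref correspond to pivot variables piv[r]
    for (r in seq_along(piv)) v[piv[r]] <- -rr$R[r, f]
    B[k, ] <- v
  }
  B
}

#' Conserved-moiety link matrix
#'
#' Splits internal metabolites into independent and dependent sets and builds
#' the link matrix `L` such that `N = L %*% N_R`, where `N_R` is the
#' stoichiometric matrix restricted to independent metabolites. The reduced
#' Jacobian and the control-coefficient system use `L` to strip structural
#' zero eigenvalues contributed by conserved moieties.
#'
#' @param net a `metabolic_network`.
#' @return list with `indep`, `dep` (metabolite ids), `L` (all internal x
#'   independent) and `NR` (independent rows of the internal matrix).
#' @export
link_matrix <- function(net) {
  N <- stoichiometric_matrix(net, "internal")
  rr <- rref_tol(t(N))            # pivot columns of t(N) = independent rows of N
  indep <- rownames(N)[rr$pivots]
  dep <- setdiff(rownames(N), indep)
  NR <- N[indep, , drop = FALSE]
  L <- matrix(0, nrow(N), length(indep), dimnames = list(rownames(N), indep))
  L[indep, ] <- diag(length(indep))
  if (length(dep)) {
    # N_D = L0 %*% N_R  =>  L0 = N_D %*% pinv(N_R)
    L0 <- N[dep, , drop = FALSE] %*% t(NR) %*% solve(NR %*% t(NR))
    L0[abs(L0) < 1e-10] <- 0
    L[dep, ] <- L0
  }
  list(indep = indep, dep = dep, L = L, NR = NR)
}

# ---------------------------------------------------------------------------
# TSV dialect: a directory with metabolites.tsv, reactions.tsv,
# regulations.tsv and network.tsv (key/value: compartments and the three
# special reaction ids). Stoichiometry strings are "met:coeff;met:coeff".

parse_stoich_string <- function(s, rid) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  out <- numeric(0)
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("reaction ", rid, ": malformed stoichiometry term '", p, "'")
    out[kv[1]] <- as.numeric(kv[2])
  }
  out
}

format_stoich_string <- function(s) {
  paste(sprintf("%s:%.15g", names(s), unname(s)), collapse = ";")
}

read_network_tsv <- function(path) {
  need <- file.path(path, c("metabolites.tsv", "reactions.tsv",
                            "regulations.tsv", "network.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss))
    stop("TSV network at '", path, "' is missing: ",
         paste(basename(miss), collapse = ", "))
  # read as character so short ids like "F" or "T" stay identifiers
  mets <- utils::read.delim(need[1], stringsAsFactors = FALSE, colClasses = "character")
  rxns <- utils::read.delim(need[2], stringsAsFactors = FALSE, colClasses = "character")
  regs <- utils::read.delim(need[3], stringsAsFactors = FALSE, colClasses = "character")
  meta <- utils::read.delim(need[4], stringsAsFactors = FALSE, colClasses = "character")
  if (!is.null(regs$hill)) regs$hill <- as.numeric(regs$hill)
  kv <- stats::setNames(meta$value, meta$key)
  mets$is_boundary <- as.logical(mets$is_boundary)
  stoich <- lapply(seq_len(nrow(rxns)), function(i)
    parse_stoich_string(rxns$stoichiometry[i], rxns$id[i]))
  names(stoich) <- rxns$id
  rxns$stoichiometry <- NULL
  for (col in c("reversible", "is_transport", "is_exchange"))
    rxns[[col]] <- as.logical(rxns[[col]])
  metabolic_network(mets, rxns, stoich,
                    regulations = if (nrow(regs)) regs else NULL,
                    compartments = strsplit(kv[["compartments"]], ",")[[1]],
                    biomass_reaction = kv[["biomass_reaction"]],
                    objective_product = kv[["objective_product"]],
                    substrate_uptake = kv[["substrate_uptake"]])
}

write_network_tsv <- function(net, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(net$metabolites, file.path(path, "metabolites.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  rx <- net$reactions
  rx$stoichiometry <- vapply(net$stoichiometry[rx$id], format_stoich_string, "")
  utils::write.table(rx, file.path(path, "reactions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(net$regulations, file.path(path, "regulations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- data.frame(key = c("compartments", "biomass_reaction",
                             "objective_product", "substrate_uptake"),
                     value = c(paste(net$compartments, collapse = ","),
                               net$biomass_reaction, net$objective_product,
                               net$substrate_uptake))
  utils::write.table(meta, file.path(path, "network.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal SBML Level 3 Version 1 core subset. Regulation is stored as
# SBO-annotated modifierSpeciesReference elements (competitive inhibition
# SBO:0000206, uncompetitive SBO:0000207, mixed SBO:0000209 (dual-mode
# inhibition), activation SBO:0000459). Notes fields carry the three special
# reaction roles.

sbo_for_mode <- c(competitive_inhibition = "SBO:0000206",
                  uncompetitive_inhibition = "SBO:0000207",
                  mixed_inhibition = "SBO:0000209",
                  activation = "SBO:0000459")

write_network_sbml <- function(net, path) {
  doc <- xml2::xml_new_root("sbml",
                            xmlns = "http://www.sbml.org/sbml/level3/version1/core",
                            level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "strainkin_model")
  ann <- xml2::xml_add_child(model, "annotation")
  xml2::xml_add_child(ann, "roles",
                      xmlns = "https://example.org/strainkin",
                      biomass = net$biomass_reaction,
                      product = net$objective_product,
                      uptake = net$substrate_uptake)
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cm in net$compartments)
    xml2::xml_add_child(lc, "compartment", id = cm, constant = "true")
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    xml2::xml_add_child(ls, "species", id = m$id, name = m$name,
                        compartment = m$compartment,
                        boundaryCondition = tolower(as.character(m$is_boundary)),
                        hasOnlySubstanceUnits = "false", constant = "false")
  }
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(net$reactions))) {
    r <- net$reactions[i, ]
    rn <- xml2::xml_add_child(lr, "reaction", id = r$id,
                              reversible = tolower(as.character(r$reversible)),
                              fast = "false")
    if (isTRUE(r$is_transport)) xml2::xml_set_attr(rn, "strainkin_transport", "true")
    if (isTRUE(r$is_exchange)) xml2::xml_set_attr(rn, "strainkin_exchange", "true")
    if (!is.na(r$gene_label)) xml2::xml_set_attr(rn, "strainkin_gene", r$gene_label)
    s <- net$stoichiometry[[r$id]]
    subs <- s[s < 0]; prods <- s[s > 0]
    if (length(subs)) {
      lrx <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(subs))
        xml2::xml_add_child(lrx, "speciesReference", species = m,
                            stoichiometry = sprintf("%.15g", -subs[[m]]),
                            constant = "true")
    }
    if (length(prods)) {
      lpx <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prods))
        xml2::xml_add_child(lpx, "speciesReference", species = m,
                            stoichiometry = sprintf("%.15g", prods[[m]]),
                            constant = "true")
    }
    regs <- net$regulations[net$regulations$target == r$id, , drop = FALSE]
    if (nrow(regs)) {
      lm <- xml2::xml_add_child(rn, "listOfModifiers")
      for (k in seq_len(nrow(regs)))
        xml2::xml_add_child(lm, "modifierSpeciesReference",
                            species = regs$regulator[k],
                            sboTerm = sbo_for_mode[[regs$mode[k]]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_network_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  comp <- xml2::xml_attr(xml2::xml_find_all(model, ".//listOfCompartments/compartment"), "id")
  sp <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), xml2::xml_attr(sp, "id"),
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    is_boundary = xml2::xml_attr(sp, "boundaryCondition") == "true",
    stringsAsFactors = FALSE)
  rx <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  stoich <- list()
  regs <- data.frame(regulator = character(), target = character(),
                     mode = character(), stringsAsFactors = FALSE)
  rxns <- data.frame(id = xml2::xml_attr(rx, "id"),
                     reversible = xml2::xml_attr(rx, "reversible") == "true",
                     is_transport = !is.na(xml2::xml_attr(rx, "strainkin_transport")),
                     is_exchange = !is.na(xml2::xml_attr(rx, "strainkin_exchange")),
                     gene_label = xml2::xml_attr(rx, "strainkin_gene"),
                     stringsAsFactors = FALSE)
  mode_for_sbo <- stats::setNames(names(sbo_for_mode), sbo_for_mode)
  for (i in seq_along(rx)) {
    rid <- rxns$id[i]
    s <- numeric(0)
    for (el in xml2::xml_find_all(rx[[i]], "./listOfReactants/speciesReference"))
      s[xml2::xml_attr(el, "species")] <- -as.numeric(xml2::xml_attr(el, "stoichiometry"))
    for (el in xml2::xml_find_all(rx[[i]], "./listOfProducts/speciesReference")) {
      m <- xml2::xml_attr(el, "species")
      s[m] <- (if (m %in% names(s)) s[[m]] else 0) +
        as.numeric(xml2::xml_attr(el, "stoichiometry"))
    }
    stoich[[rid]] <- s
    for (el in xml2::xml_find_all(rx[[i]], "./listOfModifiers/modifierSpeciesReference")) {
      sbo <- xml2::xml_attr(el, "sboTerm")
      regs <- rbind(regs, data.frame(regulator = xml2::xml_attr(el, "species"),
                                     target = rid,
                                     mode = mode_for_sbo[[sbo]],
                                     stringsAsFactors = FALSE))
    }
  }
  roles <- xml2::xml_find_first(model, ".//annotation/roles")
  metabolic_network(mets, rxns, stoich,
                    regulations = if (nrow(regs)) regs else NULL,
                    compartments = comp,
                    biomass_reaction = xml2::xml_attr(roles, "biomass"),
                    objective_product = xml2::xml_attr(roles, "product"),
                    substrate_uptake = xml2::xml_attr(roles, "uptake"))
}

#' Read a metabolic network from disk
#'
#' @param path for `format = "tsv"`, a directory holding the four-file TSV
#'   dialect written by [write_network()]; for `format = "sbml"`, an SBML
#'   file (Level 3 core subset).
#' @param format `"tsv"` or `"sbml"`.
#' @return a validated `metabolic_network`. A write/read round trip preserves
#'   stoichiometry, reversibility and regulation lists exactly.
#' @export
load_network <- function(path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  switch(format, tsv = read_network_tsv(path), sbml = read_network_sbml(path))
}

#' Write a metabolic network to disk
#' @param net a `metabolic_network`.
#' @inheritParams load_network
#' @export
write_network <- function(net, path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  switch(format, tsv = write_network_tsv(net, path),
         sbml = write_network_sbml(net, path))
}

# internal helpers used across modules
internal_met_ids <- function(net) net$metabolites$id[!net$metabolites$is_boundary]
boundary_met_ids <- function(net) net$metabolites$id[net$metabolites$is_boundary]
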