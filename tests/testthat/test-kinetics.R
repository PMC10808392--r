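test_that("rate laws are assigned by stoichiometry class", {
  net <- fb_net()
  a <- assign_rate_laws(net)
  law <- stats::setNames(a$law, a$reaction)
  expect_equal(law[["R2"]], "generalized_reversible_hill")   # uni-uni
  expect_equal(law[["HEX"]], "convenience")                  # bi-bi
  expect_equal(law[["BIO"]], "convenience")                  # multi-substrate
  expect_equal(law[["TRP"]], "mass_action")                  # periplasm -> e
  expect_equal(law[["UPT"]], "mass_action")                  # boundary carrier
  expect_equal(law[["EX_glc"]], "mass_action")
  a2 <- assign_rate_laws(net, hill = c(R2 = 2))
  expect_equal(a2$hill[a2$reaction == "R2"], 2)
  expect_error(assign_rate_laws(net, hill = c(R2 = 0.5)))
})

test_that("saturation back-calculation: K = x(1-sigma)/sigma", {
  # half saturation gives Km = x; sigma = 0.8 gives Km = x/4
  net <- fb_net()
  m <- fb_model()
  x <- exp(m$anchor$ln_conc)
  expect_equal(unname(x[["B"]] * (1 - 0.5) / 0.5), unname(x[["B"]]))
  expect_equal(2e-3 * (1 - 0.8) / 0.8, 5e-4)
  # inversion property: recomputing sigma from the stored Km returns the
  # sampled saturations to 1e-12
  set.seed(31)
  assignment <- assign_rate_laws(net)
  sat <- sample_saturations(net, assignment)
  params <- parameterize_from_saturation(net, assignment, m$anchor,
                                         fb_thermo(), sat)
  for (rid in names(sat$sites)) {
    sig <- sat$sites[[rid]]
    if (length(sig) == 0) next
    back <- x[names(sig)] / (x[names(sig)] + params$Km[[rid]])
    expect_equal(unname(back), unname(sig), tolerance = 1e-12)
  }
})

test_that("mass-action rate and equilibrium behaviour", {
  # A -> B, k = 0.5, [A] = 2: v = k [A] = 1 (irreversible limit)
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c",
                     is_boundary = c(TRUE, TRUE))
  rxns <- data.frame(id = "r", reversible = TRUE, is_transport = FALSE,
                     is_exchange = FALSE)
  net <- metabolic_network(mets, rxns, list(r = c(A = -1, B = 1)),
                           biomass_reaction = "r", objective_product = "r",
                           substrate_uptake = "r")
  RT <- 0.5925
  keq <- 1e9
  profile <- structure(list(
    fluxes = c(r = 0.5 * 2),
    ln_conc = c(A = log(2), B = log(1e-6)),
    dG = c(r = -RT * log(keq) + RT * (log(1e-6) - log(2))),
    growth_rate = 1), class = "steady_state_profile")
  th <- thermo_data(dG0 = c(r = -RT * log(keq)),
                    conc_bounds = matrix(c(1e-9, 1e-9, 10, 10), 2,
                                         dimnames = list(c("A", "B"),
                                                         c("lo", "hi"))))
  assignment <- data.frame(reaction = "r", law = "mass_action", hill = 1)
  params <- parameterize_from_saturation(net, assignment, profile, th,
                                         list(sites = list(r = numeric(0)),
                                              reg = numeric(0)))
  m <- kinetic_model(net, assignment, params, profile)
  expect_equal(params$k[["r"]], 0.5, tolerance = 1e-6)
  expect_equal(evaluate_rate(m, c(A = log(2), B = log(1e-6)))[["r"]], 1,
               tolerance = 1e-6)
  # at chemical equilibrium the rate vanishes exactly
  lnB_eq <- log(2) + log(keq)
  expect_equal(evaluate_rate(m, c(A = log(2), B = lnB_eq))[["r"]], 0)
  expect_error(evaluate_rate(m, c(A = NaN, B = 0)), "concentration")
})

test_that("anchoring holds for every sampled model", {
  for (m in fb_models()) {
    v <- evaluate_rate(m, m$anchor$ln_conc)
    ref <- m$anchor$fluxes[names(v)]
    err <- abs(v - ref) / pmax(abs(ref), 1e-12)
    expect_lt(max(err[abs(ref) >= 1e-12]), 1e-8)
    # flux balance transfers to the kinetic model
    N <- stoichiometric_matrix(m$net, "internal")
    expect_lt(max(abs(N %*% v[colnames(N)])), 1e-8)
  }
})

test_that("rate sign follows the thermodynamic driving force everywhere", {
  m <- fb_model()
  th <- fb_thermo()
  s_of <- m$net$stoichiometry
  set.seed(77)
  cache <- strainkin:::build_rate_cache(m)
  for (i in 1:1000) {
    lnx <- stats::setNames(log(runif(length(cache$mets), 1e-6, 1e-2)),
                           cache$mets)
    v <- strainkin:::evaluate_rate_cached(cache, lnx)
    for (rid in names(th$dG0)) {
      s <- s_of[[rid]]
      dG <- th$dG0[[rid]] + th$RT * sum(s * lnx[names(s)])
      if (abs(dG) > 1e-9)
        expect_true(sign(v[[rid]]) == -sign(dG) || v[[rid]] == 0)
    }
  }
})

test_that("analytic elasticities match central finite differences", {
  m <- fb_model()
  lnx <- m$anchor$ln_conc
  re <- strainkin:::rate_and_elasticity(m, lnx)
  v0 <- evaluate_rate(m, lnx)
  nz <- names(v0)[abs(v0) > 1e-9]
  h <- 1e-6
  for (j in seq_along(lnx)) {
    lp <- lnx; lp[j] <- lp[j] + h
    lm_ <- lnx; lm_[j] <- lm_[j] - h
    fd <- (log(abs(evaluate_rate(m, lp)[nz])) -
           log(abs(evaluate_rate(m, lm_)[nz]))) / (2 * h)
    expect_equal(unname(re$E[nz, j]), unname(fd), tolerance = 1e-5)
  }
})

test_that("stability pruning returns a subset of the unpruned ensemble", {
  net <- fb_net(); th <- fb_thermo()
  pruned <- suppressWarnings(
    sample_kinetic_models(net, th, fb_profiles()[1], per_profile = 6,
                          stability_prune = TRUE, seed = 21))
  free <- suppressWarnings(
    sample_kinetic_models(net, th, fb_profiles()[1], per_profile = 200,
                          stability_prune = FALSE, seed = 21,
                          max_attempts = 200))
  sig <- function(m) paste(signif(m$params$k, 12), collapse = ",")
  expect_true(all(vapply(pruned, sig, "") %in% vapply(free, sig, "")))
  # every pruned model passes an independent eigenvalue check
  for (m in pruned)
    expect_true(all(Re(eigen(compute_jacobian(m))$values) < 0))
  # reproducibility
  again <- suppressWarnings(
    sample_kinetic_models(net, th, fb_profiles()[1], per_profile = 6,
                          stability_prune = TRUE, seed = 21))
  expect_identical(vapply(pruned, sig, ""), vapply(again, sig, ""))
})

test_that("ground-truth saturations are recovered exactly by re-parameterization", {
  gt <- fb_gt()
  m <- gt$model
  # recompute sigma from Km, re-parameterize, and compare parameter sets
  x <- exp(m$anchor$ln_conc)
  sites <- lapply(m$params$Km, function(km) {
    if (length(km) == 0) return(numeric(0))
    x[names(km)] / (x[names(km)] + km)
  })
  reg_sig <- x[m$params$reg$regulator] /
    (x[m$params$reg$regulator] + m$params$reg$K)
  p2 <- parameterize_from_saturation(m$net, m$assignment, m$anchor,
                                     gt$thermo,
                                     list(sites = sites, reg = reg_sig))
  expect_equal(p2$k, m$params$k, tolerance = 1e-10)
  expect_equal(p2$Km, m$params$Km, tolerance = 1e-10)
})

test_that("kinetic models survive a JSON round trip", {
  m <- fb_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(fb_net(), f)
  expect_equal(m2$params$k, m$params$k)
  expect_equal(m2$params$Km, m$params$Km)
  expect_equal(m2$anchor$fluxes, m$anchor$fluxes)
  lnr <- m$anchor$ln_conc + 0.2
  expect_equal(evaluate_rate(m2, lnr), evaluate_rate(m, lnr))
})
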