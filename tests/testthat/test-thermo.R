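micro_net <- function(bio_coeff = 10) {
  mets <- data.frame(id = c("S_e", "S_c"), name = c("S_e", "S_c"),
                     compartment = c("e", "c"),
                     is_boundary = c(TRUE, FALSE))
  rxns <- data.frame(id = c("EX", "UPT", "BIO"),
                     reversible = c(FALSE, TRUE, FALSE),
                     is_transport = c(FALSE, TRUE, FALSE),
                     is_exchange = c(TRUE, FALSE, FALSE))
  metabolic_network(mets, rxns,
                    list(EX = c(S_e = 1), UPT = c(S_e = -1, S_c = 1),
                         BIO = stats::setNames(-bio_coeff, "S_c")),
                    biomass_reaction = "BIO", objective_product = "BIO",
                    substrate_uptake = "UPT")
}

micro_bounds <- function(net, uptake = 10) {
  fb <- matrix(c(0, 0, 0, uptake, uptake, 100), 3,
               dimnames = list(c("EX", "UPT", "BIO"), c("lb", "ub")))
  fb
}

test_that("maximal growth on a linear chain is the uptake bottleneck", {
  net <- micro_net(bio_coeff = 10)
  th <- thermo_data(dG0 = c(UPT = -2),
                    conc_bounds = matrix(c(1e-6, 1e-6, 0.1, 0.1), 2,
                                         dimnames = list(c("S_e", "S_c"),
                                                         c("lo", "hi"))))
  expect_equal(max_growth(net, th, micro_bounds(net)), 1.0, tolerance = 1e-9)
})

test_that("a thermodynamically blocked step yields zero growth", {
  net <- micro_net()
  # uptake would have to run uphill at every allowed concentration ratio
  th <- thermo_data(dG0 = c(UPT = 50),
                    conc_bounds = matrix(c(1e-6, 1e-6, 0.1, 0.1), 2,
                                         dimnames = list(c("S_e", "S_c"),
                                                         c("lo", "hi"))))
  expect_equal(max_growth(net, th, micro_bounds(net)), 0, tolerance = 1e-9)
})

test_that("TFA optimum equals plain FBA when thermodynamics is slack", {
  net <- make_toy_network("branched10")
  th <- make_toy_thermo(net, dG0 = -5)   # strongly downhill everywhere
  fb <- make_toy_flux_bounds(net)
  mu_tfa <- max_growth(net, th, fb)
  # FBA oracle: pure LP, no Gibbs-energy variables
  N <- stoichiometric_matrix(net, "internal")
  obj <- as.numeric(colnames(N) == net$biomass_reaction)
  p <- strainkin:::lp_problem(obj, A = N, sense = rep("=", nrow(N)),
                              rhs = numeric(nrow(N)), lb = fb[, "lb"],
                              ub = fb[, "ub"])
  expect_equal(mu_tfa, strainkin:::lp_solve(p)$objval, tolerance = 1e-7)
})

test_that("sampled profiles satisfy every steady-state invariant", {
  net <- fb_net(); th <- fb_thermo()
  for (p in fb_profiles()) expect_true(validate_profile(p, net, th))
  mu <- max_growth(net, th, fb_bounds())
  for (p in fb_profiles())
    expect_gte(p$growth_rate, 0.8 * mu - 1e-9)
})

test_that("sampling is reproducible and flux ranges respect variability bounds", {
  net <- make_toy_network("branched10")
  th <- make_toy_thermo(net); fb <- make_toy_flux_bounds(net)
  s1 <- sample_steady_states(net, th, fb, n = 8, seed = 4)
  s2 <- sample_steady_states(net, th, fb, n = 8, seed = 4)
  expect_identical(s1, s2)
  # flux-variability oracle: per-reaction min/max MILPs at the same growth
  mu <- max_growth(net, th, fb)
  for (rid in c("R2", "R3", "TR_p")) {
    rng <- range(vapply(s1, function(p) p$fluxes[[rid]], 0))
    for (k in 1:2) {
      prob <- strainkin:::build_tfa_lp(net, th, fb,
                                       growth_min = 0.8 * mu)
      prob$obj[] <- 0
      prob$obj[prob$tfa$iv[[rid]]] <- 1
      prob$maximize <- (k == 2)
      opt <- strainkin:::milp_solve(prob)$objval
      if (k == 1) expect_gte(rng[1], opt - 1e-6)
      if (k == 2) expect_lte(rng[2], opt + 1e-6)
    }
  }
})

test_that("displacement floors shape the sampled Gibbs energies", {
  net <- fb_net(); fb <- fb_bounds()
  th <- make_toy_thermo(net)
  rng <- dG_range(net, th, fb, "BR1")
  expect_lt(rng["lo"], -1.25)

  th125 <- apply_displacement_floor(th, "BR1", 1.25)
  s <- sample_steady_states(net, th125, fb, n = 6, seed = 9)
  expect_true(all(vapply(s, function(p) abs(p$dG[["BR1"]]) >= 1.25, TRUE)))

  # floor 0 on a floorless base is a no-op: identical samples under one seed
  base <- th; base$displacement_floor <- numeric(0)
  th0 <- apply_displacement_floor(base, "BR1", 0)
  expect_identical(sample_steady_states(net, th0, fb, n = 4, seed = 9),
                   sample_steady_states(net, base, fb, n = 4, seed = 9))

  # a floor beyond the attainable range is infeasible
  thbig <- apply_displacement_floor(th, "BR1", abs(rng["lo"]) + 50)
  expect_error(max_growth(net, thbig, fb), "infeasible")

  expect_error(apply_displacement_floor(th, "EX_glc", 1), "no Gibbs-energy")
})

test_that("unique-optimum sampling collapses to one vertex", {
  net <- make_toy_network("chain")
  th <- make_toy_thermo(net); fb <- make_toy_flux_bounds(net)
  s <- sample_steady_states(net, th, fb, n = 5, growth_fraction = 1, seed = 2)
  fl <- vapply(s, function(p) p$fluxes, s[[1]]$fluxes)
  expect_lt(max(apply(fl, 1, function(z) diff(range(z)))), 1e-6)
})

test_that("profiles serialize to CSV", {
  d <- withr::local_tempdir()
  path <- write_profiles_csv(fb_profiles(), fb_thermo(),
                             file.path(d, "profiles.csv"))
  tab <- read.csv(path)
  expect_setequal(unique(tab$kind), c("reaction", "metabolite"))
  expect_equal(sum(tab$kind == "reaction"),
               length(fb_profiles()) * nrow(fb_net()$reactions))
})
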