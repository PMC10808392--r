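test_that("textbook elasticities come out of the rate laws", {
  # irreversible Michaelis-Menten limit of the reversible Hill law:
  # substrate elasticity 1 - sigma (0.5 at half saturation)
  mets <- data.frame(id = c("A_e", "X"), name = c("A_e", "X"),
                     compartment = c("e", "c"),
                     is_boundary = c(TRUE, FALSE))
  rxns <- data.frame(id = "r", reversible = FALSE, is_transport = FALSE,
                     is_exchange = FALSE)
  net <- metabolic_network(mets, rxns, list(r = c(A_e = -1, X = 1)),
                           biomass_reaction = "r", objective_product = "r",
                           substrate_uptake = "r")
  for (sig in c(0.5, 0.8)) {
    profile <- structure(list(fluxes = c(r = 1),
                              ln_conc = c(A_e = log(1e-3), X = log(1e-3)),
                              dG = c(r = -10), growth_rate = 1),
                         class = "steady_state_profile")
    th <- thermo_data(dG0 = c(r = -12),
                      conc_bounds = matrix(c(1e-9, 1e-9, 1, 1), 2,
                                           dimnames = list(mets$id,
                                                           c("lo", "hi"))))
    params <- parameterize_from_saturation(
      net, assign_rate_laws(net), profile, th,
      list(sites = list(r = c(A_e = sig, X = 1e-4)), reg = numeric(0)))
    m <- kinetic_model(net, assign_rate_laws(net), params, profile)
    E <- strainkin:::rate_and_elasticity(m, profile$ln_conc)$E
    expect_equal(E["r", "A_e"], 1 - sig, tolerance = 1e-3)
  }
})

test_that("two-step linear chain control coefficients match the closed form", {
  # A_e -> X -> B_e with saturable steps: C_1 = e2/(e2-e1), C_2 = -e1/(e2-e1)
  mets <- data.frame(id = c("A_e", "X", "B_e"), name = c("A_e", "X", "B_e"),
                     compartment = c("e", "c", "e"),
                     is_boundary = c(TRUE, FALSE, TRUE))
  rxns <- data.frame(id = c("r1", "r2"), reversible = TRUE,
                     is_transport = FALSE, is_exchange = FALSE)
  net <- metabolic_network(mets, rxns,
                           list(r1 = c(A_e = -1, X = 1),
                                r2 = c(X = -1, B_e = 1)),
                           biomass_reaction = "r2", objective_product = "r2",
                           substrate_uptake = "r1")
  RT <- 0.5925
  th <- thermo_data(dG0 = c(r1 = -3, r2 = -3),
                    conc_bounds = matrix(c(rep(1e-8, 3), rep(1, 3)), 3,
                                         dimnames = list(mets$id,
                                                         c("lo", "hi"))))
  ln <- c(A_e = log(1e-2), X = log(1e-3), B_e = log(1e-4))
  dG <- vapply(c(r1 = "r1", r2 = "r2"), function(r) {
    s <- net$stoichiometry[[r]]
    th$dG0[[r]] + RT * sum(s * ln[names(s)])
  }, 0)
  profile <- structure(list(fluxes = c(r1 = 1, r2 = 1), ln_conc = ln,
                            dG = dG, growth_rate = 1),
                       class = "steady_state_profile")
  assignment <- assign_rate_laws(net)
  set.seed(5)
  sat <- sample_saturations(net, assignment)
  params <- parameterize_from_saturation(net, assignment, profile, th, sat)
  m <- kinetic_model(net, assignment, params, profile)
  cc <- control_coefficients(m)
  e <- strainkin:::rate_and_elasticity(m, ln)$E[, "X"]
  closed <- c(e[["r2"]], -e[["r1"]]) / (e[["r2"]] - e[["r1"]])
  expect_equal(unname(cc$C_v["r1", ]), closed, tolerance = 1e-10)
  expect_equal(unname(cc$C_v["r2", ]), closed, tolerance = 1e-10)
})

test_that("summation theorems hold across a large sampled ensemble", {
  net <- fb_net(); th <- fb_thermo()
  models <- suppressWarnings(
    sample_kinetic_models(net, th, fb_profiles(), per_profile = 17,
                          stability_prune = FALSE, seed = 13))
  expect_gte(length(models), 50)
  for (m in models) {
    cc <- tryCatch(control_coefficients(m), error = function(e) NULL)
    if (is.null(cc)) next
    expect_lt(max(abs(rowSums(cc$C_v) - 1)), 1e-8)
    expect_lt(max(abs(rowSums(cc$C_x))), 1e-8)
  }
})

test_that("control coefficients predict nonlinear flux responses", {
  models <- fb_models()[1:3]
  dlne <- log(1.001)
  for (m in models) {
    cc <- control_coefficients(m)
    v0 <- evaluate_rate(m, m$anchor$ln_conc)
    nz <- names(v0)[abs(v0) > 1e-9]
    for (e in c("BR1", "HEX", "BR2")) {
      m2 <- m
      m2$params$k[e] <- m$params$k[e] * exp(dlne)
      ss <- relax_to_steady_state(m2, t_end = 80)
      obs <- log(ss$fluxes[nz] / v0[nz]) / dlne
      expect_lt(max(abs(cc$C_v[nz, e] - obs)), 1e-2)
    }
  }
})

test_that("top-k target ranking orders by |coefficient| with sign directions", {
  cc <- structure(list(C_yield = c(a = 0.5, b = -0.9, c = 0.1),
                       C_v = matrix(c(0.5, -0.9, 0.1), 1,
                                    dimnames = list("p", c("a", "b", "c"))),
                       product = "p"),
                  class = "control_coefficients")
  top <- top_k_targets(cc, "yield", 2)
  expect_equal(top$enzyme, c("b", "a"))
  expect_equal(top$direction, c("down", "up"))
  expect_equal(nrow(top_k_targets(cc, "yield", 10)), 3)
  # deterministic lexicographic tie-break
  cc$C_yield <- c(z = 0.5, a = 0.5, m = -0.5)
  expect_equal(top_k_targets(cc, "yield", 3)$enzyme, c("a", "m", "z"))
})

test_that("near-equilibrium diagnostics flag small displacements", {
  m <- fb_model()
  rep_ <- near_equilibrium_report(m, threshold = 1e9)
  expect_true(all(c("reaction", "dG", "displacement") %in% names(rep_)))
  expect_true(all(abs(rep_$dG) >= 0.1 - 1e-9))  # toy displacement floor
})
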