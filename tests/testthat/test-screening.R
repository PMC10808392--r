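test_that("reduced Jacobian matches closed forms and finite differences", {
  # one-species linear system dx/dt = -k x with k = 2
  mets <- data.frame(id = c("A_e", "X", "B_e"), name = c("A_e", "X", "B_e"),
                     compartment = c("e", "c", "e"),
                     is_boundary = c(TRUE, FALSE, TRUE))
  rxns <- data.frame(id = c("in_", "out"), reversible = FALSE,
                     is_transport = FALSE, is_exchange = c(TRUE, FALSE))
  net <- metabolic_network(mets, rxns,
                           list(in_ = c(X = 1), out = c(X = -1, B_e = 1)),
                           biomass_reaction = "out", objective_product = "out",
                           substrate_uptake = "in_")
  profile <- structure(list(fluxes = c(in_ = 2e-3, out = 2e-3),
                            ln_conc = c(A_e = log(1), X = log(1e-3),
                                        B_e = log(1e-9)),
                            dG = c(in_ = NA, out = NA), growth_rate = 2e-3),
                       class = "steady_state_profile")
  assignment <- data.frame(reaction = c("in_", "out"), law = "mass_action",
                           hill = 1)
  params <- parameterize_from_saturation(
    net, assignment, profile,
    thermo_data(dG0 = numeric(0),
                conc_bounds = matrix(c(rep(1e-12, 3), rep(10, 3)), 3,
                                     dimnames = list(mets$id, c("lo", "hi")))),
    list(sites = list(in_ = numeric(0), out = numeric(0)), reg = numeric(0)))
  m <- kinetic_model(net, assignment, params, profile, scale_int = 1)
  expect_equal(params$k[["out"]], 2, tolerance = 1e-9)   # v = k x anchored
  expect_equal(compute_jacobian(m), matrix(-2), tolerance = 1e-9)

  # sampled model: Jacobian matches a central finite-difference oracle
  mm <- fb_model()
  lm0 <- link_matrix(mm$net)
  J <- compute_jacobian(mm)
  xss <- exp(mm$anchor$ln_conc)
  g <- function(xi) {
    xf <- xss
    xf[lm0$indep] <- xi
    xf[lm0$dep] <- xss[lm0$dep] +
      drop(lm0$L[lm0$dep, , drop = FALSE] %*% (xi - xss[lm0$indep]))
    lnf <- mm$anchor$ln_conc
    lnf[names(xf)] <- log(xf)
    strainkin:::internal_rhs(mm, lnf)[lm0$indep]
  }
  x0 <- xss[lm0$indep]
  Jfd <- matrix(0, length(x0), length(x0))
  for (j in seq_along(x0)) {
    hj <- 1e-6 * x0[j]
    xp <- x0; xp[j] <- xp[j] + hj
    xm <- x0; xm[j] <- xm[j] - hj
    Jfd[, j] <- (g(xp) - g(xm)) / (2 * hj)
  }
  expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-5)
  # the conserved ATP/ADP pair reduces the dimension by one
  expect_equal(nrow(J), nrow(stoichiometric_matrix(mm$net, "internal")) - 1)
})

test_that("dominant time constant formula and flags", {
  expect_equal(dominant_time_constant(c(-1, -0.05, -2)), 20)
  expect_equal(dominant_time_constant(-1 / 24), 24)  # per-minute eigenvalue
  unstable <- dominant_time_constant(c(-1, 0.1))
  expect_true(is.na(unstable))
  expect_false(attr(unstable, "stable"))
})

test_that("recovery fraction reproduces the settling rules", {
  expect_equal(recovery_fraction(5, 1), 0.9933, tolerance = 1e-4)
  # doubling time at mu = 0.32/h is 130 min; tau = 24 min recovers >= 99.5%
  td <- doubling_time(0.32)
  expect_equal(round(td), 130)
  expect_gte(recovery_fraction(td, 24), 0.995)
  expect_gte(recovery_fraction(td, 43), 0.95)
  expect_equal(doubling_time(log(2)), 60)
  expect_error(doubling_time(0))
  # monotonicity
  expect_true(all(diff(recovery_fraction(seq(0.1, 5, 0.1), 1)) > 0))
  expect_true(all(diff(recovery_fraction(1, seq(0.1, 5, 0.1))) < 0))
})

test_that("eigenvalue time constant matches simulated relaxation", {
  m <- fb_model()
  es <- eigen_summary(m)
  expect_true(es$stable)
  J <- compute_jacobian(m)
  eg <- eigen(J)
  i <- which.min(abs(Re(eg$values)))
  tau <- 1 / abs(Re(eg$values[i]))
  lm0 <- link_matrix(m$net)
  vec <- Re(eg$vectors[, i]); vec <- vec / max(abs(vec))
  ids <- rownames(stoichiometric_matrix(m$net, "internal"))
  xf <- exp(m$anchor$ln_conc[ids])
  xi <- xf[lm0$indep] * (1 + 0.01 * vec)
  xf[lm0$indep] <- xi
  xf[lm0$dep] <- exp(m$anchor$ln_conc[lm0$dep]) +
    drop(lm0$L[lm0$dep, , drop = FALSE] %*%
           (xi - exp(m$anchor$ln_conc[lm0$indep])))
  out <- strainkin:::integrate_internal(m, log(xf), tau * 6, n_out = 150)
  dev <- apply(abs(sweep(out[, -1], 2, m$anchor$ln_conc[ids])), 1, max)
  sel <- which(out[, 1] > tau & dev > 1e-8)
  fit <- stats::lm(log(dev[sel]) ~ out[sel, 1])
  expect_equal(-1 / coef(fit)[[2]], tau, tolerance = 0.05)
})

test_that("linear-dynamics screening is threshold-monotone", {
  models <- fb_models()
  s_inf <- screen_linear_dynamics(models, tau_max = Inf)
  stable <- vapply(models, function(m) eigen_summary(m)$stable, TRUE)
  expect_equal(s_inf$retained, which(stable))
  s24 <- screen_linear_dynamics(models, tau_max = 24 / 60)
  s43 <- screen_linear_dynamics(models, tau_max = 43 / 60)
  expect_true(all(s24$retained %in% s43$retained))
})

test_that("concentration-robustness screen separates mono- and bistable models", {
  m <- fb_model()
  expect_true(screen_concentration_robustness(m, k_fold = 1, n = 2, seed = 1))
  expect_identical(
    screen_concentration_robustness(m, k_fold = 2, n = 4, seed = 5),
    screen_concentration_robustness(m, k_fold = 2, n = 4, seed = 5))
  gb <- make_ground_truth_model(make_toy_network("bistable_toy"), seed = 1)
  expect_true(screen_concentration_robustness(gb$model, k_fold = 1.3, n = 5,
                                              horizon = 5, seed = 1))
  expect_false(screen_concentration_robustness(gb$model, k_fold = 20, n = 5,
                                               horizon = 5, seed = 1))
})

test_that("fermentation-fit screen accepts the generating model", {
  gt <- fb_gt(); cfg <- fb_config(); data <- fb_data()
  fit <- screen_fermentation_fit(gt$model, data, cfg)
  expect_true(fit)
  met <- attr(fit, "metrics")
  expect_lt(met$biomass_rel_err, 0.05)
  expect_lt(met$product_rel_err, 0.10)
  expect_lt(met$fermentation_time, 20)
  # zero tolerance passes only for an exact (noiseless) resimulation
  noiseless <- generate_pseudo_experiment(gt$model, cfg, noise_cv = 0,
                                          seed = 1)
  expect_true(screen_fermentation_fit(gt$model, noiseless, cfg,
                                      tol_biomass = 1e-12,
                                      tol_product = 1e-12))
  expect_false(isTRUE(screen_fermentation_fit(gt$model, data, cfg,
                                              tol_biomass = 0,
                                              tol_product = 0)))
  bad <- data; bad$time <- rev(bad$time)
  expect_error(screen_fermentation_fit(gt$model, bad, cfg), "non-decreasing")
  expect_error(screen_fermentation_fit(gt$model, data[, 1:2], cfg),
               "columns")
})

test_that("enzyme-robustness screen: degenerate settings are permissive", {
  gt <- fb_gt(); cfg <- fb_config()
  expect_true(screen_enzyme_robustness(gt$model, cfg, cv = 0, n = 2, seed = 1))
  expect_true(screen_enzyme_robustness(gt$model, cfg, cv = 0.3, n = 3,
                                       growth_floor = 0, seed = 1))
})
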