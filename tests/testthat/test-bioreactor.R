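test_that("batch coupling reproduces anchor rates at t = 0 and is deterministic", {
  gt <- fb_gt(); cfg <- fb_config()
  m <- gt$model
  ids <- rownames(stoichiometric_matrix(m$net, "internal"))
  lnx0 <- m$anchor$ln_conc
  lnx0[names(cfg$medium)] <- log(cfg$medium)
  v0 <- evaluate_rate(m, lnx0)
  expect_equal(v0, m$anchor$fluxes[names(v0)], tolerance = 1e-10)
  t1 <- simulate_batch(m, cfg)
  t2 <- simulate_batch(m, cfg)
  expect_identical(t1$biomass, t2$biomass)
  expect_identical(t1$conc, t2$conc)
})

test_that("zero inoculum freezes the medium", {
  gt <- fb_gt()
  cfg <- fb_config()
  cfg0 <- bioreactor_config(initial_biomass = 0, medium = cfg$medium,
                            t_end = 5, molar_mass = cfg$molar_mass,
                            include_dilution = FALSE)
  tr <- simulate_batch(gt$model, cfg0, n_out = 20)
  for (sp in names(cfg$medium))
    expect_equal(unname(tr$conc[, sp]), rep(unname(cfg$medium[[sp]]), 20),
                 tolerance = 1e-8)
  expect_equal(max(tr$biomass), 0)
})

test_that("total carbon is conserved in a carbon-closed batch", {
  net <- make_toy_network("carbon_closed")
  gcc <- make_ground_truth_model(net, seed = 2)
  cfg <- make_toy_bioreactor_config(gcc$model, include_dilution = TRUE,
                                    t_end = 10)
  tr <- simulate_batch(gcc$model, cfg)
  carbon <- attr(net, "carbon"); cbio <- attr(net, "carbon_biomass")
  ids <- rownames(stoichiometric_matrix(net, "internal"))
  bnd <- strainkin:::boundary_met_ids(net)
  cell_vol <- 0.001 / gcc$model$scale_int
  total <- vapply(seq_along(tr$time), function(i) {
    sum(carbon[bnd] * tr$conc[i, bnd]) +
      tr$biomass[i] * cell_vol * sum(carbon[ids] * tr$conc[i, ids]) +
      tr$biomass[i] * 0.001 * cbio
  }, 0)
  expect_lt((max(total) - min(total)) / total[1], 0.001)
  # the per-reaction carbon audit also balances
  for (rid in setdiff(net$reactions$id, net$biomass_reaction)) {
    s <- net$stoichiometry[[rid]]
    expect_equal(sum(s * carbon[names(s)]), 0)
  }
})

test_that("apply_design scales activities and respects its contract", {
  m <- fb_model()
  expect_identical(apply_design(m, data.frame(enzyme = character(0),
                                              direction = character(0),
                                              fold = numeric(0))), m)
  d <- data.frame(enzyme = c("BR1", "BR2"), direction = c("up", "down"),
                  fold = c(5, 2))
  m2 <- apply_design(m, d)
  expect_equal(m2$params$k[["BR1"]], 5 * m$params$k[["BR1"]])
  expect_equal(m2$params$k[["BR2"]], m$params$k[["BR2"]] / 2)
  expect_error(apply_design(m, data.frame(enzyme = c("BR1", "BR1"),
                                          direction = c("up", "down"),
                                          fold = c(5, 5))),
               "one direction")
  expect_error(apply_design(m, data.frame(enzyme = "nope", direction = "up",
                                          fold = 2)), "unknown enzyme")
  # monotone response on a linear chain: upregulating one pathway step
  # raises the steady product flux
  cg <- chain_gt()
  up <- apply_design(cg$model, data.frame(enzyme = "S3", direction = "up",
                                          fold = 2))
  ss <- relax_to_steady_state(up)
  expect_gt(ss$fluxes[["TRP"]], cg$model$anchor$fluxes[["TRP"]])
})

test_that("regulation editing relieves feedback inhibition", {
  m <- fb_gt()$model
  v0 <- evaluate_rate(m, m$anchor$ln_conc)
  m_scaled <- edit_regulation(m, "BR1", "F", "scale", factor = 1)
  expect_equal(evaluate_rate(m_scaled, m$anchor$ln_conc), v0)
  m_free <- edit_regulation(m, "BR1", "F", "remove")
  v1 <- evaluate_rate(m_free, m$anchor$ln_conc)
  expect_gte(v1[["BR1"]], v0[["BR1"]])
  # removing the inhibition raises the steady branch flux
  ss <- relax_to_steady_state(m_free)
  expect_gt(ss$fluxes[["BR1"]], v0[["BR1"]])
  expect_error(edit_regulation(m, "R2", "F", "remove"), "no regulation")
})

test_that("sensitivity analysis bookkeeping is exact", {
  gt <- fb_gt(); cfg <- fb_config()
  models <- list(gt$model)
  d <- data.frame(enzyme = c("BR1", "BR2"), direction = c("up", "down"),
                  fold = c(3, 2))
  s0 <- sensitivity_analysis(models, d, cfg, spread = 0, reps = 2, seed = 1)
  expect_equal(s0$trials$titer[1], s0$trials$titer[2], tolerance = 1e-12)
  s1 <- sensitivity_analysis(models, d, cfg, spread = 0.5, reps = 3,
                             mode = "each", seed = 2)
  expect_setequal(unique(s1$trials$perturbed), c("BR1", "BR2"))
  expect_equal(nrow(s1$trials), 2 * 1 * 3)
  expect_equal(unname(s1$mean_titer["BR1"]),
               mean(s1$trials$titer[s1$trials$perturbed == "BR1"]))
  s2 <- sensitivity_analysis(models, d, cfg, spread = 0.5, reps = 3,
                             mode = "all", seed = 3)
  expect_equal(unique(s2$trials$perturbed), "BR1+BR2")
  expect_equal(unname(s2$mean_titer), mean(s2$trials$titer, na.rm = TRUE))
})

test_that("design clustering recovers planted membership structure", {
  expect_equal(cluster_designs(list(c("a", "b"), c("a", "b")))$assignment,
               c(1L, 1L))
  two <- cluster_designs(list(c("a", "b"), c("c", "d")), n_clusters = 2)
  expect_equal(length(unique(two$assignment)), 2)
  # three planted motifs, several designs each, small within-motif variation
  motifs <- list(c("a1", "a2", "a3"), c("b1", "b2", "b3"), c("c1", "c2", "c3"))
  designs <- list()
  extras <- list(c("x1"), c("x2"), c("x3"))
  for (k in 1:3) for (j in 1:3)
    designs[[length(designs) + 1L]] <- c(motifs[[k]], extras[[j]])
  cl <- cluster_designs(designs, n_clusters = 3)
  planted <- rep(1:3, each = 3)
  expect_equal(length(unique(cl$assignment)), 3)
  # same-motif designs always share a cluster
  for (k in 1:3)
    expect_equal(length(unique(cl$assignment[planted == k])), 1)
})

test_that("nonlinear ranking puts the bottleneck-relieving design first", {
  gt <- fb_gt(); cfg <- fb_config()
  models <- list(gt$model)
  cands <- list(
    data.frame(enzyme = "BR1", direction = "up", fold = 4),      # planted fix
    data.frame(enzyme = "RGN", direction = "up", fold = 4),
    data.frame(enzyme = "HEX", direction = "down", fold = 2),
    data.frame(enzyme = character(0), direction = character(0),
               fold = numeric(0)))                               # no-op
  tab <- rank_designs_nonlinear(models, cands, cfg)
  expect_equal(tab$design[1], 1)
  ref <- final_titer(simulate_batch(gt$model, cfg))
  noop <- tab[tab$design == 4, ]
  expect_equal(noop$median_titer, ref, tolerance = 1e-9)
  # single design, single model: the row is recomputable
  one <- rank_designs_nonlinear(models, cands[1], cfg)
  tr <- simulate_batch(apply_design(gt$model, cands[[1]]), cfg)
  expect_equal(one$median_titer, final_titer(tr), tolerance = 1e-9)
  expect_equal(one$median_productivity, productivity(tr), tolerance = 1e-9)
})

test_that("trajectories export as tidy CSV", {
  gt <- fb_gt()
  tr <- simulate_batch(gt$model, fb_config(), n_out = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  tab <- read.csv(f)
  expect_setequal(unique(tab$species), c("biomass", colnames(tr$conc)))
  expect_equal(nrow(tab), 10 * (1 + ncol(tr$conc)))
})
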