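test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(true_lfc = c(A = 0.5, B = 0), seed = 42)
  s1 <- simulate_studies(cfg)
  s2 <- simulate_studies(cfg)
  expect_identical(s1$studies[[1]]$matrix, s2$studies[[1]]$matrix)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_studies(simulation_config(true_lfc = c(A = 0.5, B = 0),
                                           seed = 43))
  expect_false(identical(s1$studies[[1]]$matrix, s3$studies[[1]]$matrix))
})

test_that("the noiseless limit returns the planted effect almost exactly", {
  cfg <- simulation_config(true_lfc = c(A = -0.48), tau2 = 0,
                           noise_sd = 1e-8, seed = 1)
  sim <- simulate_studies(cfg)
  eff <- effects_for_gene(sim$studies, "A")
  expect_equal(eff$lfc, rep(-0.48, 13), tolerance = 1e-6)
})

test_that("the default design matches the 13-cohort compendium structure", {
  d <- default_study_design()
  expect_equal(nrow(d), 13L)
  expect_equal(range(c(d$n_control, d$n_case)), c(4L, 443L))
  cfg <- simulation_config(true_lfc = c(G = 0), seed = 2)
  sim <- simulate_studies(cfg)
  meta <- studies_metadata(sim$studies)
  expect_equal(meta$n_control, d$n_control)
  expect_equal(meta$n_case, d$n_case)
  expect_equal(meta$country, d$country)
})

test_that("covariate slopes enter the true study effects linearly", {
  cfg <- simulation_config(true_lfc = c(G = 0), tau2 = 0, noise_sd = 1e-8,
                           covariate_slopes = list(study_age = 0.1),
                           seed = 5)
  sim <- simulate_studies(cfg)
  eff <- effects_for_gene(sim$studies, "G")
  meta <- studies_metadata(sim$studies)
  expect_equal(eff$lfc, 0.1 * meta$study_age, tolerance = 1e-6)
})

test_that("between-study variance tau2 spreads the realized study effects", {
  cfg <- simulation_config(true_lfc = c(G = 0), tau2 = 0.3,
                           noise_sd = 1e-8, seed = 6)
  sim <- simulate_studies(cfg)
  eff <- effects_for_gene(sim$studies, "G")
  expect_gt(var(eff$lfc), 0.05)
  expect_equal(eff$lfc, sim$truth$delta[match(eff$study_id,
                                              sim$truth$study_id)],
               tolerance = 1e-6)
})

test_that("DerSimonian-Laird recovers a planted tau2 on average", {
  design <- data.frame(study_id = sprintf("s%02d", 1:50),
                       n_control = 50L, n_case = 50L,
                       country = "USA", study_age = 5L)
  est <- vapply(1:200, function(r) {
    cfg <- simulation_config(design = design, true_lfc = c(G = 0),
                             tau2 = 0.3, noise_sd = 1, seed = 5000 + r)
    sim <- simulate_studies(cfg)
    random_effects(effects_for_gene(sim$studies, "G"))$tau2
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3) / 0.3, 0.5)
})

test_that("planted gene-set overlaps are exact and infeasible requests error", {
  query <- sprintf("Q%02d", 1:26)
  gsc <- simulate_genesets(sizes = c(544, 215), planted_query = query,
                           planted_overlaps = c(17, 12),
                           universe_size = 3000, seed = 9)
  res <- fisher_enrich(query, gsc)
  expect_equal(sort(res$overlap), c(12L, 17L))
  expect_equal(sort(unname(lengths(gsc$sets))), c(215L, 544L))
  expect_equal(round(jaccard(544, 26, 17), 3), 0.031)
  expect_error(simulate_genesets(sizes = 10, planted_query = query,
                                 planted_overlaps = 11,
                                 universe_size = 3000), "overlap")
  gsc2 <- simulate_genesets(sizes = c(544, 215), planted_query = query,
                            planted_overlaps = c(17, 12),
                            universe_size = 3000, seed = 9)
  expect_identical(gsc$sets, gsc2$sets)
})

test_that("zero planted overlap leaves no enrichment signal", {
  query <- sprintf("Q%02d", 1:20)
  gsc <- simulate_genesets(sizes = rep(50, 8), planted_query = query,
                           planted_overlaps = rep(0, 8),
                           universe_size = 500, seed = 10)
  res <- fisher_enrich(query, gsc)
  expect_true(all(res$overlap == 0L))
  expect_true(all(res$p_value == 1))
})

test_that("planted relation class composition is matched exactly", {
  rel <- simulate_relations(30, n_suppressed = 13, n_activated = 6, seed = 4)
  cc <- count_classes(classify_contradirectional(rel, "REG1"))
  expect_equal(cc$classes[["suppressed_disease_promoter"]], 13L)
  expect_equal(cc$classes[["activated_disease_inhibitor"]], 6L)
  expect_equal(cc$classes[["concordant_excluded"]], 11L)
  all_conc <- simulate_relations(10, 0, 0, seed = 4)
  cc0 <- count_classes(classify_contradirectional(all_conc, "REG1"))
  expect_equal(cc0$classes[["suppressed_disease_promoter"]], 0L)
  expect_equal(cc0$classes[["activated_disease_inhibitor"]], 0L)
  expect_identical(simulate_relations(10, 2, 3, seed = 7),
                   simulate_relations(10, 2, 3, seed = 7))
})
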