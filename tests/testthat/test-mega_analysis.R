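test_that("fixed-effects pooling matches the closed form", {
  single <- fixed_effects(eff_df(0.7, 0.2))
  expect_equal(single$pooled_lfc, 0.7)
  expect_equal(single$pooled_se, 0.2)

  two <- fixed_effects(eff_df(c(1, 3), c(1, 1)))
  expect_equal(two$pooled_lfc, 2)
  expect_equal(two$pooled_se, 1 / sqrt(2), tolerance = 1e-12)

  same <- fixed_effects(eff_df(rep(0.42, 5), runif(5, 0.1, 1)))
  expect_equal(same$pooled_lfc, 0.42)
})

test_that("heterogeneity statistics match hand closed forms", {
  h <- heterogeneity(eff_df(c(0, 2), c(1, 1)))
  expect_equal(h$Q, 2, tolerance = 1e-10)
  expect_equal(h$df, 1)
  expect_equal(h$ISq, 50, tolerance = 1e-10)
  expect_equal(h$Qp, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-10)

  id <- heterogeneity(eff_df(c(1.3, 1.3), c(0.5, 0.5)))
  expect_equal(id$Q, 0)
  expect_equal(id$ISq, 0)
  expect_equal(id$Qp, 1)

  expect_error(heterogeneity(eff_df(1, 1)), "at least 2")
})

test_that("DerSimonian-Laird matches the hand oracle and reduces to fixed", {
  r <- random_effects(eff_df(c(0, 2), c(1, 1)))
  expect_equal(r$tau2, 1, tolerance = 1e-10)   # C = 1, Q - df = 1
  expect_equal(r$pooled_lfc, 1, tolerance = 1e-10)
  expect_equal(r$pooled_se, 1, tolerance = 1e-10)

  # homogeneous data: Q <= df forces tau2 = 0 and the fixed answer exactly
  hom <- eff_df(c(0.5, 0.52, 0.48), c(1, 1, 1))
  expect_lte(heterogeneity(hom)$Q, heterogeneity(hom)$df)
  r0 <- random_effects(hom)
  f0 <- fixed_effects(hom)
  expect_identical(r0$tau2, 0)
  expect_equal(r0$pooled_lfc, f0$pooled_lfc, tolerance = 1e-15)
  expect_equal(r0$pooled_se, f0$pooled_se, tolerance = 1e-15)
})

test_that("pooled closed forms match brute-force evaluation for k <= 4", {
  set.seed(31)
  for (k in 2:4) {
    for (rep in 1:10) {
      lfc <- sample(-3:3, k, replace = TRUE)
      se <- sample(1:4, k, replace = TRUE) / 2
      eff <- eff_df(lfc, se)
      w <- 1 / se^2
      mu <- sum(w * lfc) / sum(w)
      f <- fixed_effects(eff)
      expect_equal(f$pooled_lfc, mu, tolerance = 1e-12)
      expect_equal(f$pooled_se, 1 / sqrt(sum(w)), tolerance = 1e-12)
      Q <- sum(w * (lfc - mu)^2)
      C <- sum(w) - sum(w^2) / sum(w)
      tau2 <- max(0, (Q - (k - 1)) / C)
      ws <- 1 / (se^2 + tau2)
      r <- random_effects(eff)
      expect_equal(r$tau2, tau2, tolerance = 1e-12)
      expect_equal(r$pooled_lfc, sum(ws * lfc) / sum(ws), tolerance = 1e-12)
      expect_equal(r$pooled_se, 1 / sqrt(sum(ws)), tolerance = 1e-12)
    }
  }
})

test_that("pooling agrees with metafor as an independent reference", {
  set.seed(99)
  lfc <- rnorm(8); se <- runif(8, 0.2, 1)
  eff <- eff_df(lfc, se)
  fe <- suppressWarnings(metafor::rma(yi = lfc, sei = se, method = "FE"))
  f <- fixed_effects(eff)
  expect_equal(f$pooled_lfc, as.numeric(fe$beta), tolerance = 1e-10)
  expect_equal(f$pooled_se, fe$se, tolerance = 1e-10)
  dl <- suppressWarnings(metafor::rma(yi = lfc, sei = se, method = "DL"))
  r <- random_effects(eff)
  expect_equal(r$tau2, dl$tau2, tolerance = 1e-10)
  expect_equal(r$pooled_lfc, as.numeric(dl$beta), tolerance = 1e-10)
  expect_equal(r$pooled_se, dl$se, tolerance = 1e-10)
  expect_equal(r$het$Q, dl$QE, tolerance = 1e-10)
  expect_equal(r$het$Qp, dl$QEp, tolerance = 1e-10)
})

test_that("the pooled fixed estimate is a convex combination and ISq is bounded", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(2:10, 1)
    eff <- eff_df(rnorm(k, 0, 2), runif(k, 0.1, 2))
    f <- fixed_effects(eff)
    expect_gte(f$pooled_lfc, min(eff$lfc))
    expect_lte(f$pooled_lfc, max(eff$lfc))
    h <- heterogeneity(eff)
    expect_gte(h$ISq, 0)
    expect_lt(h$ISq, 100)
    expect_gte(h$Qp, 0)
    expect_lte(h$Qp, 1)
  }
})

test_that("ISq increases with Q at fixed df", {
  spreads <- c(0.5, 1, 2, 4, 8)
  stats <- lapply(spreads, function(s) heterogeneity(eff_df(c(-s, 0, s),
                                                            c(1, 1, 1))))
  Q <- vapply(stats, `[[`, numeric(1), "Q")
  ISq <- vapply(stats, `[[`, numeric(1), "ISq")
  ord <- order(Q)
  expect_true(all(diff(Q[ord]) > 0))
  expect_true(all(diff(ISq[ord][Q[ord] > 2]) > 0))  # strictly, once Q > df
  expect_true(all(ISq[Q <= 2] == 0))
})

test_that("model selection follows the ISq = 0 rule, with k = 1 flagged", {
  hom <- meta_analyze(eff_df(c(0.5, 0.52, 0.48), c(1, 1, 1)))
  expect_equal(hom$model, "fixed")
  expect_equal(hom$het$ISq, 0)
  het <- meta_analyze(eff_df(c(-2, 0, 2), c(0.1, 0.1, 0.1)))
  expect_equal(het$model, "random")
  expect_gt(het$het$ISq, 0)
  one <- meta_analyze(eff_df(0.7, 0.2))
  expect_equal(one$model, "fixed")
  expect_true(one$het_undefined)
  expect_null(one$het)
})

test_that("zero-variance estimates get a substitute se instead of infinite weight", {
  eff <- eff_df(c(1, 1.2, 1.1), c(0, 0.4, 0.5))
  expect_message(f <- fixed_effects(eff), "zero-variance")
  expect_true(is.finite(f$pooled_lfc) && f$pooled_se > 0)
  # substituted se = min positive se / 10 dominates the weighting
  expect_lt(abs(f$pooled_lfc - 1), 0.05)
})

test_that("meta_result behaves like a model object", {
  m <- meta_analyze(eff_df(c(-0.5, -0.4, -0.6), c(0.1, 0.2, 0.15)))
  expect_s3_class(m, "meta_result")
  expect_named(coef(m), "pooled_lfc")
  ci <- confint(m)
  expect_lt(ci[1], coef(m))
  expect_gt(ci[2], coef(m))
  expect_output(print(m), "Mega-analysis")
  expect_output(print(summary(m)), "CI")
  df <- as.data.frame(m)
  expect_equal(df$pooled_lfc, m$pooled_lfc)
  expect_equal(df$ISq, m$het$ISq)
})

test_that("multi-gene mega-analysis pools each gene and appends BH", {
  cfg <- simulation_config(true_lfc = c(A = 1, B = 0, C = -1),
                           design = default_study_design()[1:4, ], seed = 3)
  sim <- simulate_studies(cfg)
  tab <- mega_analyze_genes(sim$studies)
  expect_equal(tab$gene, c("A", "B", "C"))
  expect_true(all(tab$k == 4L))
  expect_equal(tab$p_bh, p.adjust(tab$p_value, "BH"))
  expect_gt(tab$pooled_lfc[tab$gene == "A"], 0.5)
  expect_lt(tab$pooled_lfc[tab$gene == "C"], -0.5)
})
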