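test_that("ratio estimator pools counts across clusters", {
  expect_equal(ratio_estimator(cluster_summary(x = c(2, 1), y = c(2, 0))),
               2 / 3)
  expect_equal(ratio_estimator(cluster_summary(x = c(4, 6), y = c(4, 6))), 1)
  expect_error(ratio_estimator(cluster_summary(integer(0), integer(0))),
               "no cluster")
})

test_that("anova_icc reproduces the hand-computed one-way ANOVA", {
  v <- c(1, 1, 1, 1, 0, 0, 0, 0, 0)
  g <- rep(c("A", "B", "C"), each = 3)
  e <- anova_icc(v, g)
  expect_equal(e$msb, 7 / 9, tolerance = 1e-12)
  expect_equal(e$msw, 1 / 9, tolerance = 1e-12)
  expect_equal(e$F, 7)
  expect_equal(e$rho, 2 / 3, tolerance = 1e-12)
  expect_equal(e$a, 3L)
  expect_equal(e$n, 9L)
  # equal sizes: k0 equals the mean size and both k conventions agree
  expect_equal(e$k, 3)
  expect_equal(anova_icc(v, g, k_method = "mean")$rho, e$rho)
})

test_that("F statistic agrees with stats::aov on a random instance", {
  set.seed(202)
  inst <- random_small_instance()
  fit <- stats::aov(inst$values ~ factor(inst$groups))
  f_aov <- summary(fit)[[1]]$`F value`[1]
  expect_equal(anova_icc(inst$values, inst$groups)$F, f_aov,
               tolerance = 1e-10)
})

test_that("the k = n/a form equals the F computing formula, unequal sizes too", {
  set.seed(303)
  for (i in 1:20) {
    inst <- random_small_instance()
    e <- anova_icc(inst$values, inst$groups, k_method = "mean")
    a <- e$a; n <- e$n
    expect_equal(e$rho,
                 ((e$F - 1) * a / n) / (1 + (e$F - 1) * a / n),
                 tolerance = 1e-12)
  }
})

test_that("degenerate ANOVA inputs are flagged, not raised", {
  # perfect within-cluster homogeneity: MSW = 0
  e <- anova_icc(c(1, 1, 0, 0), c("A", "A", "B", "B"))
  expect_equal(e$F, Inf)
  expect_equal(e$rho, 1)
  expect_true("degenerate" %in% e$flags)

  # perfect heterogeneity: MSB = 0, raw estimate negative, clamped for report
  e2 <- anova_icc(c(1, 0, 1, 0), c("A", "A", "B", "B"))
  expect_lt(e2$rho, 0)
  expect_equal(e2$rho_reported, 0)
  expect_equal(e2$ci_low, 0)

  # all values identical
  expect_warning(e3 <- anova_icc(rep(1, 6), rep(c("A", "B"), each = 3)),
                 "identical")
  expect_equal(e3$rho, 0)
  expect_true("constant" %in% e3$flags)

  expect_error(anova_icc(1:3, c("A", "A", "A")), "at least 2 clusters")
  expect_error(anova_icc(c(1, 0), c("A", "B")), "n > a")
})

test_that("confidence interval brackets the estimate and respects [0, 1]", {
  set.seed(404)
  co <- generate_cohort(sim_scenario(mu = 0.3, rho = 0.1,
                                     cluster_sizes = rep(40, 15)))
  e <- estimate_variable(co, generated_var_spec())$icc
  expect_lte(e$ci_low, e$rho_reported)
  expect_gte(e$ci_high, e$rho_reported)
  expect_gte(e$ci_low, 0)
  expect_lte(e$ci_high, 1)
  expect_gt(e$se, 0)
  # the plain Wald variant is symmetric around the raw estimate
  w <- anova_icc(co$data$outcome, co$data$cluster, ci_method = "wald")
  expect_equal(w$ci_high - w$rho, w$rho - w$ci_low, tolerance = 1e-9)
})

test_that("design_effect matches direct arithmetic on the toy clusters", {
  s <- cluster_summary(x = c(3, 3, 3), y = c(3, 1, 0))
  d <- design_effect(s)
  expect_equal(d$var_actual, 42 / 486, tolerance = 1e-12)
  expect_equal(d$var_srs, 20 / 648, tolerance = 1e-12)
  expect_equal(d$deff, 2.8, tolerance = 1e-12)
})

test_that("design_effect handles flat and degenerate ratio patterns", {
  # all cluster ratios equal: no between-cluster variance
  expect_equal(design_effect(cluster_summary(x = c(4, 4), y = c(2, 2)))$deff,
               0)
  # pooled ratio at the boundary: variance under SRS is zero
  d <- design_effect(cluster_summary(x = c(3, 3), y = c(3, 3)))
  expect_true(is.na(d$deff))
  expect_true("degenerate" %in% d$flags)
  expect_error(design_effect(cluster_summary(x = 5, y = 2)),
               "at least 2 clusters")
})

test_that("deff is invariant to cluster labels; r to count scaling", {
  set.seed(505)
  inst <- random_small_instance()
  cnt <- instance_counts(inst)
  d1 <- design_effect(cluster_summary(cnt$x, cnt$y))
  perm <- sample(length(cnt$x))
  d2 <- design_effect(cluster_summary(cnt$x[perm], cnt$y[perm],
                                      cluster_id = sprintf("Z%d", perm)))
  expect_equal(d2$deff, d1$deff, tolerance = 1e-12)
  expect_equal(ratio_estimator(cluster_summary(3L * cnt$x, 3L * cnt$y)),
               ratio_estimator(cluster_summary(cnt$x, cnt$y)))
})

test_that("estimators match the from-definition oracle on random instances", {
  set.seed(606)
  for (i in 1:200) {
    inst <- random_small_instance()
    o <- oracle_anova(inst$values, inst$groups)
    e <- anova_icc(inst$values, inst$groups)
    expect_equal(e$F, o$F, tolerance = 1e-12)
    expect_equal(e$rho, o$rho_k0, tolerance = 1e-12)
    cnt <- instance_counts(inst)
    od <- oracle_deff(cnt$x, cnt$y)
    d <- design_effect(cluster_summary(cnt$x, cnt$y))
    expect_equal(d$deff, od$deff, tolerance = 1e-12)
  }
})

test_that("sample-size recalculation follows the cluster-correction formula", {
  expect_equal(recalc_sample_size(a = 27, icc = 0.5, deff = 2)$n_star, 81L)
  expect_equal(recalc_sample_size(a = 27, icc = 0.077, deff = 1)$n_star, 27L)
  expect_error(recalc_sample_size(a = 27, icc = 0, deff = 2),
               "non-positive ICC")
  expect_error(recalc_sample_size(a = 27, icc = -0.1, deff = 2),
               "non-positive ICC")
})

test_that("estimate_variable composes summaries, ICC and DEFF", {
  co <- make_toy_cohort()
  vr <- estimate_variable(co, toy_spec())
  expect_equal(vr$P, 100 * 4 / 9)
  expect_equal(vr$icc$rho, 2 / 3, tolerance = 1e-12)
  expect_equal(vr$deff$deff, 2.8, tolerance = 1e-12)
  expect_equal(vr$n_a, 3L)
  row <- as.data.frame(vr)
  expect_equal(row$P_percent, 44.4)
  expect_equal(row$ICC, 0.667)
  expect_equal(row$DEFF, 2.8)
})

test_that("full-denominator variables on the network design report n_a = 354", {
  co <- generate_cohort(sim_scenario(mu = 0.2, rho = 0.05, seed = 7))
  vr <- estimate_variable(co, generated_var_spec())
  expect_equal(vr$n_a, 354L)
  expect_equal(vr$a_eff, 27L)
  expect_equal(vr$valid_n, 9555L)
})

test_that("a sparse subpopulation drives n_a down to its own denominator", {
  # 9 abortion cases spread over 3 clusters; variable valid only there
  df <- data.frame(cluster = rep(c("A", "B", "C"), times = c(100, 100, 100)),
                   abortion = "0", dc = "0")
  idx <- c(1:3, 101:103, 201:203)
  df$abortion[idx] <- "1"
  df$dc[idx] <- c("1", "1", "0", "1", "1", "1", "0", "1", "1")
  spec <- var_spec("dc", "process", rule_equals(1),
                   subpopulation = list(variable = "abortion",
                                        rule = rule_equals(1)))
  vr <- estimate_variable(as_cohort(df), spec)
  expect_equal(vr$valid_n, 9L)
  expect_equal(vr$n_a, 3L)
})

test_that("equal-cluster deff tracks the classical 1 + (b - 1) rho identity", {
  set.seed(707)
  b <- 10L
  rho <- 0.2
  sc <- sim_scenario(mu = 0.4, rho = rho, cluster_sizes = rep(b, 30))
  deffs <- replicate(200, {
    vr <- estimate_variable(generate_cohort(sc), generated_var_spec())
    vr$deff$deff
  })
  expect_equal(mean(deffs), 1 + (b - 1) * rho, tolerance = 0.1)
})

test_that("under independence the reported ICC stays near zero", {
  set.seed(808)
  sc <- sim_scenario(mu = 0.25, rho = 0)
  hits <- replicate(100, {
    vr <- estimate_variable(generate_cohort(sc), generated_var_spec())
    vr$icc$rho_reported < 0.05
  })
  expect_gte(mean(hits), 0.9)
})
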