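# Quartile grouping, covariate-adjusted tests, Bonferroni control, partial
# correlation and power.

test_that("quartile grouping follows the inclusive interpolation convention", {
  g <- assign_groups(1:100)
  expect_equal(oracle_quantile7(1:100, 0.25), 25.75)
  expect_equal(oracle_quantile7(1:100, 0.75), 75.25)
  expect_equal(as.vector(table(g)), c(25L, 50L, 25L))
  expect_equal(levels(g), c("low", "middle", "high"))
  # boundary ties go to the outer groups
  x <- c(rep(10, 30), rep(20, 40), rep(30, 30))
  gt <- assign_groups(x)
  expect_true(all(gt[x == 10] == "low"))
  expect_true(all(gt[x == 30] == "high"))
  expect_error(assign_groups(rep(7, 50)), "degenerate")
  expect_error(assign_groups(1:5), "at least 8")
})

test_that("a cohort-shaped sample splits into three sensible groups", {
  cfg <- sim_config(n_subjects_per_group = c(44, 71, 38), n_nodes = 2,
                    n_trials = 2, seed = 15)
  rec <- generate_cohort(cfg, signals = FALSE)$records
  g <- assign_groups(rec$ctq_total)
  expect_equal(nlevels(droplevels(g)), 3L)
  expect_equal(sum(g == "low") + sum(g == "high"), 153 - sum(g == "middle"))
  expect_lt(abs((sum(g == "low") + sum(g == "high")) / 153 - 0.5), 0.1)
  # quartile labels agree with the generative labels away from boundaries
  expect_gt(mean(g == rec$group_label), 0.9)
})

test_that("two-group ANCOVA without covariates is the pooled t test squared", {
  set.seed(5)
  v <- rnorm(30)
  g <- rep(c("a", "b"), each = 15)
  v[16:30] <- v[16:30] + 0.8
  at <- ancova_group_test(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(at$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(at$p, tt$p.value, tolerance = 1e-12)
})

test_that("ANCOVA matches a from-scratch normal-equations oracle", {
  set.seed(8)
  n <- 9
  g <- factor(rep(c("low", "middle", "high"), each = 3),
              levels = c("low", "middle", "high"))
  z <- cbind(rnorm(n), rnorm(n))
  v <- rnorm(n) + 0.5 * z[, 1] + c(0, 0.4, 0.9)[as.integer(g)]
  at <- ancova_group_test(v, g, z)
  or <- oracle_ancova(v, g, z)
  expect_equal(at$F, or$F, tolerance = 1e-10)
  expect_equal(at$partial_eta_sq, or$partial_eta_sq, tolerance = 1e-10)
  expect_equal(at$p, or$p, tolerance = 1e-10)
  expect_equal(at$df_effect, or$df_effect)
  expect_equal(at$df_error, or$df_error)
})

test_that("partial eta squared is invariant to affine response rescaling", {
  set.seed(9)
  v <- rnorm(40)
  g <- sample(c("low", "middle", "high"), 40, replace = TRUE)
  z <- rnorm(40)
  a1 <- ancova_group_test(v, g, z)
  a2 <- ancova_group_test(5 - 3.2 * v, g, z)
  expect_equal(a1$partial_eta_sq, a2$partial_eta_sq, tolerance = 1e-12)
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
})

test_that("null ANCOVA keeps its nominal type-I rate", {
  set.seed(12)
  n <- 45
  g <- rep(c("low", "middle", "high"), each = 15)
  rej <- mean(replicate(2000, {
    z <- matrix(rnorm(2 * n), n)
    ancova_group_test(rnorm(n), g, z)$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("rank-deficient designs and tiny groups are rejected", {
  v <- rnorm(20)
  g <- rep(c("a", "b"), each = 10)
  z <- cbind(1:20, 2 * (1:20))
  expect_error(ancova_group_test(v, g, z), "rank-deficient|collinear")
  expect_error(ancova_group_test(v[1:3], c("a", "a", "b")), "at least 2")
})

test_that("the multivariate flag adds a Wilks test on index matrices", {
  set.seed(14)
  n <- 60
  g <- rep(c("low", "middle", "high"), each = 20)
  vm <- matrix(rnorm(4 * n), n) + c(0, 0.2, 0.8)[rep(1:3, each = 20)]
  z <- rnorm(n)
  at <- ancova_group_test(vm, g, z, multivariate = TRUE)
  expect_true(!is.null(at$wilks))
  expect_true(at$wilks$wilks > 0 && at$wilks$wilks < 1)
  expect_lt(at$wilks$p, 0.05)
})

test_that("Bonferroni thresholds reproduce the published family cut-offs", {
  expect_identical(bonferroni_threshold(0.05, 16), 0.003125)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(round(bonferroni_threshold(0.05, 314), 6), 0.000159)
  expect_equal(round(bonferroni_threshold(0.05, 60), 6), 0.000833)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("post-hoc pairwise tests are adjusted, capped and directional", {
  set.seed(17)
  n <- 60
  g <- factor(rep(c("low", "middle", "high"), each = 20),
              levels = c("low", "middle", "high"))
  z <- rnorm(n)
  # planted low-vs-high shift, middle in between but close to low
  v <- rnorm(n, sd = 0.5) + c(0, 0.1, 1.2)[as.integer(g)] + 0.3 * z
  ph <- posthoc_pairwise(v, g, z)
  expect_equal(nrow(ph), 3L)
  expect_true(all(ph$p_adj <= 1))
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_equal(ph$pair[which.min(ph$p_adj)], "low-high")
  # identical group means: adjusted p should be far from significant
  set.seed(18)
  null_p <- replicate(200, {
    ph0 <- posthoc_pairwise(rnorm(n), g, rnorm(n))
    min(ph0$p_adj)
  })
  expect_lt(mean(null_p < 0.05), 0.1)
  expect_gt(mean(null_p), 0.4)
  expect_error(posthoc_pairwise(v[c(1, 21, 41)],
                                g[c(1, 21, 41)]), "at least 2")
})

test_that("partial correlation residualizes exactly", {
  set.seed(20)
  n <- 30
  z <- matrix(rnorm(3 * n), n)
  x <- rnorm(n) + z %*% c(1, -0.5, 0.2)
  y <- rnorm(n) + z %*% c(-0.3, 0.8, 0.1) - 0.4 * scale(x)[, 1]
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r_partial, oracle_partial_r(x, y, z), tolerance = 1e-12)
  expect_equal(pc$df, n - 3 - 2)
  # no covariates: plain Pearson, matched against cor.test
  ct <- cor.test(as.vector(x), as.vector(y))
  pc0 <- partial_correlation(x, y)
  expect_equal(pc0$r_partial, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc0$p, ct$p.value, tolerance = 1e-10)
  # y equal to a covariate is fully explained
  expect_lt(abs(partial_correlation(x, z[, 2], z)$r_partial), 1e-10)
  expect_error(partial_correlation(x[1:4], y[1:4], z[1:4, ]), "n >")
})

test_that("ANOVA power follows the noncentral F law", {
  expect_equal(anova_power(0, 150, 3, 0.05), 0.05, tolerance = 1e-12)
  p <- anova_power(0.25, 153, 3, 0.05)
  expect_equal(p, oracle_ncf_power(0.25, 153, 3, 0.05), tolerance = 1e-4)
  expect_equal(anova_power(0.13, 153, 3, 0.05),
               oracle_ncf_power(0.13, 153, 3, 0.05), tolerance = 1e-4)
  # monotone in n and in f
  ns <- c(30, 60, 120, 240)
  expect_true(all(diff(vapply(ns, function(n)
    anova_power(0.25, n, 3, 0.05), numeric(1))) > 0))
  fs <- c(0.1, 0.2, 0.4, 0.8)
  expect_true(all(diff(vapply(fs, function(f)
    anova_power(f, 100, 3, 0.05), numeric(1))) > 0))
  expect_error(anova_power(0.2, 3, 3, 0.05), "degrees of freedom")
})

test_that("network_group_analysis assembles the full index-by-band table", {
  cfg <- desk_pipeline_config(seed = 99)
  coh <- generate_cohort(cfg$sim)
  cc <- cohort_connectivity(coh$epochs)
  m <- cohort_metrics(cc)
  rec <- coh$records
  rec$group_label <- assign_groups(rec$ctq_total)
  res <- network_group_analysis(m$global, rec)
  expect_s3_class(res, "network_group_stats")
  expect_equal(nrow(res$table), 16L)
  expect_equal(res$threshold, 0.003125)
  expect_true(all(c("p_low_high", "diff_low_high",
                    "partial_eta_sq") %in% names(res$table)))
  expect_true(all(res$table$p >= 0 & res$table$p <= 1))
  expect_true(all(res$table$partial_eta_sq >= 0 &
                    res$table$partial_eta_sq <= 1))
})
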