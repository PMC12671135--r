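test_that("trapezoid AUC matches the printed formula and simple shapes", {
  expect_equal(trapezoid_auc(c(0, 10), c(1.0, 0.5)), 7.5)
  expect_equal(trapezoid_auc(c(0, 10, 20), c(1, 1, 1)), 20.0)
  expect_error(trapezoid_auc(0, 1), "input error")
  expect_error(trapezoid_auc(c(0, 5, 5), c(1, 1, 1)), "increasing")
})

test_that("trapezoid AUC approximates the closed-form exponential integral", {
  d <- seq(0, 60, by = 2)
  v <- exp(-d / 30)
  exact <- 30 * (1 - exp(-2))
  expect_lt(abs(trapezoid_auc(d, v) - exact) / exact, 0.005)
})

test_that("trapezoid AUC is linear in viability and additive over intervals", {
  set.seed(12)
  d <- sort(runif(8, 0, 50)); d[1] <- 0
  v1 <- runif(8); v2 <- runif(8)
  expect_equal(trapezoid_auc(d, 2 * v1 + 3 * v2),
               2 * trapezoid_auc(d, v1) + 3 * trapezoid_auc(d, v2))
  expect_equal(trapezoid_auc(d[1:4], v1[1:4]) + trapezoid_auc(d[4:8], v1[4:8]),
               trapezoid_auc(d, v1))
})

test_that("AUC comparison handles identical, separated and degenerate groups", {
  same <- compare_auc(c(7, 8, 9), c(7, 8, 9))
  expect_equal(same$t, 0); expect_equal(same$p, 1); expect_equal(same$stars, "NS")
  sep <- compare_auc(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sep$df, 4)
  expect_lt(sep$p, 0.01); expect_equal(sep$stars, "**")
  flat <- compare_auc(c(5, 5), c(5, 5))
  expect_equal(flat$p, 1)
  flat2 <- compare_auc(c(5, 5), c(6, 6))
  expect_equal(flat2$p, 0)
  expect_error(compare_auc(1, c(2, 3)), "input error")
})

test_that("the pooled t-test p agrees with an exhaustive permutation oracle", {
  set.seed(99)
  for (rep in 1:5) {
    a <- rnorm(3, 1); b <- rnorm(3, 0)
    obs <- compare_auc(a, b)
    pool <- c(a, b)
    combs <- combn(6, 3)
    tstat <- apply(combs, 2, function(ix)
      abs(t.test(pool[ix], pool[-ix], var.equal = TRUE)$statistic))
    p_perm <- mean(tstat >= abs(obs$t) - 1e-12)
    # the t p-value should agree with the exact permutation p up to the
    # permutation test's resolution (20 relabelings)
    expect_lt(abs(obs$p - p_perm), 1 / 10 + 0.15)
  }
})

test_that("stress survival averages per-replicate treated/untreated ratios", {
  sv <- stress_survival(data.frame(cfu_untreated = 200, cfu_treated = 50))
  expect_equal(sv$percent_survival, 25)
  expect_equal(stress_survival(
    data.frame(cfu_untreated = 100, cfu_treated = 0))$mean_percent, 0)
  five <- stress_survival(data.frame(cfu_untreated = rep(100, 5),
                                     cfu_treated = rep(50, 5)))
  expect_equal(five$mean_percent, 50)
  expect_equal(five$n_replicates, 5L)
  expect_warning(
    mixed <- stress_survival(data.frame(cfu_untreated = c(100, 0),
                                        cfu_treated = c(25, 3))), "dropped")
  expect_equal(mixed$mean_percent, 25)
  expect_error(suppressWarnings(stress_survival(
    data.frame(cfu_untreated = 0, cfu_treated = 1))), "input error")
})

test_that("Fisher's exact test matches symmetry cases and stats::fisher.test", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1.0)
  set.seed(4)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 12), 2)
    p <- fisher_exact(tab)
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-10)
    # symmetric under swapping rows and under swapping columns
    expect_equal(p, fisher_exact(tab[2:1, ]), tolerance = 1e-12)
    expect_equal(p, fisher_exact(tab[, 2:1]), tolerance = 1e-12)
  }
  # all-or-none table: point masses under the <=-observed rule
  tab <- matrix(c(0, 10, 10, 0), 2)
  expect_equal(fisher_exact(tab), fisher.test(tab)$p.value, tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "input error")
})

test_that("ANOVA F matches a closed-form recomputation and flags the shifted group", {
  g <- list(a = rep(1:3, 1), b = rep(1:3, 1), c = rep(1:3, 1))
  res0 <- anova_posthoc(g)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  set.seed(5)
  g2 <- list(x = rnorm(30), y = rnorm(30), z = rnorm(30, 5))
  res <- anova_posthoc(g2, bonferroni = TRUE)
  expect_lt(res$p, 0.01)
  ph <- res$posthoc
  expect_lt(ph$p[ph$group_a == "x" & ph$group_b == "z"], 0.01)
  expect_lt(ph$p[ph$group_a == "y" & ph$group_b == "z"], 0.01)
  expect_gt(ph$p[ph$group_a == "x" & ph$group_b == "y"], 0.05)
  expect_true(all(ph$p_bonferroni >= ph$p))
  # closed form: F = between-MS / within-MS
  k <- 3; n <- 30
  gm <- mean(unlist(g2))
  msb <- sum(vapply(g2, function(v) n * (mean(v) - gm)^2, 0)) / (k - 1)
  msw <- sum(vapply(g2, function(v) sum((v - mean(v))^2), 0)) / (k * n - k)
  expect_equal(res$F, msb / msw, tolerance = 1e-10)
  expect_error(anova_posthoc(list(a = 1, b = 1:3)), "input error")
})

test_that("decay-rate fitting recovers the generator's lambda", {
  cfg <- synth_config(seed = 8)
  gen <- generate_cfu_dataset(cfg)
  fit <- fit_decay_rate(gen$cfu)
  for (cond in names(cfg$cfu_lambda)) {
    lam <- fit$lambda_per_day[fit$condition == cond]
    expect_lt(abs(lam - cfg$cfu_lambda[[cond]]) / cfg$cfu_lambda[[cond]], 0.15)
  }
  expect_equal(fit$half_life_days, log(2) / fit$lambda_per_day)
})

test_that("replicate AUCs and condition comparison work end to end", {
  cfg <- synth_config(seed = 9)
  gen <- generate_cfu_dataset(cfg)
  viab <- cfu_viability(gen$cfu)
  aucs <- replicate_aucs(viab)
  expect_equal(nrow(aucs), 2L * cfg$cfu_replicates)
  cmp <- compare_auc(aucs$auc[aucs$condition == "4C"],
                     aucs$auc[aucs$condition == "37C"])
  expect_lt(cmp$p, 0.01)   # slow vs fast decay separates clearly
  expect_gt(cmp$mean_a, cmp$mean_b)
})
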