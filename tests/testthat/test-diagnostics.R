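test_that("ROC handles the canonical fixtures", {
  # perfectly separated classes
  r <- roc_analysis(c(1, 2, 10, 11), c(0, 0, 1, 1), n_boot = 0)
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_equal(r$cutoff, 10)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  # values carry no information: all equal
  r2 <- roc_analysis(rep(3, 6), c(0, 1, 0, 1, 0, 1), n_boot = 0)
  expect_equal(r2$auc, 0.5)

  # 4-point interleaved fixture: brute-force over all 4 pairs gives 0.75
  r3 <- roc_analysis(c(1, 3, 2, 4), c(0, 0, 1, 1), n_boot = 0)
  expect_equal(r3$auc, oracle_auc_pairs(c(2, 4), c(1, 3)))
  expect_equal(r3$auc, 0.75)
  # J ties at 0.5 for cutoffs 2 and 4; higher specificity wins -> 4
  expect_equal(r3$cutoff, 4)

  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "non-empty")
})

test_that("trapezoidal AUC equals pairwise concordance and the cutoff survives an exhaustive scan", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    lab <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    vals <- round(rnorm(n, ifelse(lab, 0.5, 0), 1), sample(0:2, 1))  # ties likely
    r <- roc_analysis(vals, lab, n_boot = 0)
    expect_equal(r$auc, oracle_auc_pairs(vals[lab], vals[!lab]),
                 tolerance = 1e-12)
    sc <- oracle_youden_scan(vals, lab)
    expect_equal(r$cutoff, sc$cutoff)
    expect_equal(r$youden_j, sc$j, tolerance = 1e-12)
    expect_equal(r$youden_j, r$sensitivity + r$specificity - 1,
                 tolerance = 1e-12)
  }
})

test_that("ROC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (i in 1:10) {
    lab <- c(TRUE, FALSE, runif(18) > 0.5)
    vals <- rnorm(20, ifelse(lab, 1, 0))
    r <- roc_analysis(vals, lab, n_boot = 0)
    pr <- pROC::roc(lab, vals, direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  }
})

test_that("bootstrap AUC CI is seeded, ordered and brackets the point estimate", {
  set.seed(1)
  lab <- runif(40) > 0.5
  vals <- rnorm(40, ifelse(lab, 1, 0))
  r1 <- roc_analysis(vals, lab, n_boot = 500, seed = 7)
  r2 <- roc_analysis(vals, lab, n_boot = 500, seed = 7)
  expect_identical(r1$ci_auc, r2$ci_auc)
  expect_lt(r1$ci_auc[1], r1$auc)
  expect_gt(r1$ci_auc[2], r1$auc)
})

test_that("ICC(2,1) reproduces the hand-ANOVA fixture and its invariances", {
  mat <- matrix(c(2.1, 2.3,
                  3.0, 3.4,
                  4.2, 4.0,
                  5.5, 5.9), nrow = 4, byrow = TRUE)
  ic <- icc_agreement(mat)
  # frozen from the aov() mean-squares oracle: MSR 4.413333, MSC 0.08, MSE 0.04
  expect_equal(ic$msr, 4.4133333333, tolerance = 1e-9)
  expect_equal(ic$msc, 0.08, tolerance = 1e-9)
  expect_equal(ic$mse, 0.04, tolerance = 1e-9)
  expect_equal(ic$icc, 0.9776453055, tolerance = 1e-9)
  expect_true(ic$icc_ci[1] < ic$icc && ic$icc < ic$icc_ci[2])

  # independent route: recompute the mean squares with aov()
  d <- data.frame(y = as.vector(mat), subj = factor(rep(1:4, 2)),
                  rater = factor(rep(1:2, each = 4)))
  ms <- anova(stats::aov(y ~ subj + rater, data = d))
  expect_equal(ic$msr, ms["subj", "Mean Sq"], tolerance = 1e-12)
  expect_equal(ic$mse, ms["Residuals", "Mean Sq"], tolerance = 1e-12)

  # identical columns with subject variation: exactly 1 (flagged)
  expect_warning(one <- icc_agreement(cbind(1:5, 1:5)), "exactly 1")
  expect_identical(one$icc, 1)
  # shift invariance and the <= 1 bound
  expect_equal(icc_agreement(mat + 100)$icc, ic$icc, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(rnorm(30), ncol = 2)
    expect_lte(icc_agreement(m)$icc, 1)
  }
  # zero total variance is undefined
  expect_warning(und <- icc_agreement(matrix(3, 4, 2)), "undefined")
  expect_true(is.na(und$icc))
})

test_that("independent reader noise drives ICC toward zero", {
  set.seed(77)
  iccs <- replicate(20, icc_agreement(matrix(rnorm(400), ncol = 2))$icc)
  expect_lt(abs(mean(iccs)), 0.1)
})

test_that("Bland-Altman summaries match hand arithmetic and are antisymmetric", {
  ba <- bland_altman(c(1, 2, 3), c(2, 2, 5))
  expect_equal(ba$mean_diff, -1)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa, c(-1 - 1.96, -1 + 1.96))
  expect_equal(ba$loa_1sd, c(-2, 0))

  ba_sw <- bland_altman(c(2, 2, 5), c(1, 2, 3))
  expect_equal(ba_sw$mean_diff, -ba$mean_diff)
  expect_equal(ba_sw$sd_diff, ba$sd_diff)

  id <- bland_altman(c(4, 5, 6), c(4, 5, 6))
  expect_equal(id$mean_diff, 0)
  expect_equal(id$sd_diff, 0)
  expect_error(bland_altman(1, 1), "pairs")
})

test_that("Kruskal-Wallis p agrees with a permutation oracle and handles degeneracy", {
  groups <- list(c(1.2, 3.4, 2.2), c(2.8, 4.1, 3.9), c(6.0, 5.5, 7.2))
  kw <- kruskal_wallis(groups)
  orc <- oracle_kw_perm_p(groups, n_perm = 2e4, seed = 3)
  expect_equal(kw$statistic, orc$h, tolerance = 1e-9)
  # the chi-square approximation deviates from the exact permutation null by
  # up to ~0.05 at n = 9; allow that systematic bias on top of the MC error
  se <- sqrt(orc$p * (1 - orc$p) / 2e4)
  expect_lt(abs(kw$p_value - orc$p), 3 * se + 0.06)

  # identical multisets in every group: H near 0, p near 1
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  kw0 <- kruskal_wallis(same)
  expect_lt(kw0$statistic, 1e-9)
  expect_gt(kw0$p_value, 0.99)

  expect_warning(deg <- kruskal_wallis(list(c(2, 2), c(2, 2))), "tied")
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), ">= 1")
})

test_that("H increases monotonically as two groups separate", {
  base <- c(1, 2, 3, 4, 5)
  hs <- vapply(c(0, 1, 2, 4, 8), function(shift)
    kruskal_wallis(list(base, base + shift))$statistic, numeric(1))
  expect_true(all(diff(hs) >= 0))
})

test_that("Dunn post hoc matches the hand-rank oracle with Bonferroni capping", {
  gd <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(50, 60, 70))
  dn <- dunn_posthoc(gd)
  # frozen from the hand-rank oracle (rank means 2.667/4.333/8, tie-corrected)
  z_ab <- dn$z[dn$group1 == "a" & dn$group2 == "b"]
  z_ac <- dn$z[dn$group1 == "a" & dn$group2 == "c"]
  expect_equal(z_ab, -0.7516460280, tolerance = 1e-9)
  expect_equal(z_ac, -2.4052672896, tolerance = 1e-9)
  expect_equal(dn$p_adj, pmin(1, dn$p_raw * 3), tolerance = 1e-12)
  # the extreme group drives the signal: a-c is the only adjusted-significant
  # pair at n = 3 per group, and both pairs involving c rank below a-b
  p_ab <- dn$p_adj[dn$group1 == "a" & dn$group2 == "b"]
  p_ac <- dn$p_adj[dn$group1 == "a" & dn$group2 == "c"]
  p_bc <- dn$p_adj[dn$group1 == "b" & dn$group2 == "c"]
  expect_lt(p_ac, 0.05)
  expect_true(p_ac < p_bc && p_bc < p_ab)
  expect_gt(p_ab, 0.5)

  # five groups: m = 10, raw 0.02 -> adjusted 0.20; identical groups -> all 1
  g5 <- list(a = 1:3, b = 1:3, c = 1:3, d = 1:3, e = 1:3)
  dn5 <- dunn_posthoc(g5)
  expect_equal(nrow(dn5), 10L)
  expect_true(all(dn5$p_adj == 1))
  expect_equal(min(1, 0.02 * 10), 0.20)
  expect_equal(dn5$p_adj, pmin(1, dn5$p_raw * 10))
})

test_that("one-way ANOVA matches closed forms and flags degeneracy", {
  # hand fixture frozen from the between/within mean-square oracle
  g <- list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8))
  a <- one_way_anova(g)
  expect_equal(a$statistic, 21, tolerance = 1e-9)
  expect_equal(a$p_value, 0.001953125, tolerance = 1e-9)

  # two-group F equals the squared pooled-variance t
  set.seed(12)
  x <- rnorm(8); y <- rnorm(9, 0.7)
  a2 <- one_way_anova(list(x, y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(a2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p_value, tt$p.value, tolerance = 1e-10)

  # equal group means: F ~ 0
  expect_lt(one_way_anova(list(c(1, 3), c(2, 2), c(1, 3)))$statistic, 1e-10)
  expect_warning(dg <- one_way_anova(list(c(2, 2), c(3, 3))), "variance")
  expect_true(is.na(dg$statistic))
})

test_that("normality screening separates Gaussian from skewed samples", {
  set.seed(8)
  norm_p <- ks_normality(rnorm(200), n_sim = 500, seed = 2)$p_value
  skew_p <- ks_normality(rexp(200)^2, n_sim = 500, seed = 2)$p_value
  expect_gt(norm_p, 0.05)
  expect_lt(skew_p, 0.01)
  # seeded reproducibility
  x <- rnorm(50)
  expect_identical(ks_normality(x, n_sim = 200, seed = 4)$p_value,
                   ks_normality(x, n_sim = 200, seed = 4)$p_value)
})

test_that("Lilliefors distance agrees with the established implementation", {
  skip_if_not_installed("nortest")
  set.seed(21)
  x <- rnorm(60, 5, 2)
  d <- ks_normality(x, n_sim = 50, seed = 1)$statistic
  expect_equal(unname(d), unname(nortest::lillie.test(x)$statistic),
               tolerance = 1e-12)
  expect_warning(ks_normality(rep(2, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2)), ">= 5")
})

test_that("per-stage descriptives mirror the clinical summary format", {
  co <- data.frame(stage = c("F0", "F0", "F0", "F1", "F2"),
                   v = c(2, 4, 9, 5, 7))
  d <- descriptive_by_stage(co, "v")
  f0 <- d[d$stage == "F0", ]
  expect_equal(f0$n, 3)
  expect_equal(f0$mean, 5)
  expect_equal(f0$sd, sd(c(2, 4, 9)))
  expect_equal(f0$median, 4)
  expect_equal(c(f0$q1, f0$q3), unname(quantile(c(2, 4, 9), c(.25, .75))))
  expect_equal(c(f0$min, f0$max), c(2, 9))
  # single-value stage: SD 0, degenerate IQR
  f1 <- d[d$stage == "F1", ]
  expect_equal(f1$sd, 0)
  expect_equal(f1$q1, f1$q3)
})
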