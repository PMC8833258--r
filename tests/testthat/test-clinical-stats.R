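pop_sd_test <- function(v) sqrt(mean((v - mean(v))^2))

test_that("average_baseline_vas and classify_responders", {
  expect_equal(average_baseline_vas(c(6, 7, 8)), 7)
  expect_equal(average_baseline_vas(5.5), 5.5)
  set.seed(40)
  triple <- runif(3, 0, 10)
  expect_equal(average_baseline_vas(triple), sum(triple) / 3)
  expect_error(average_baseline_vas(numeric()), "no baseline")
  expect_error(average_baseline_vas(c(5, 11)), "0, 10")

  # threshold rule: exactly 20% is a responder, 15% is not
  tab <- data.frame(subject_id = c("a", "b"),
                    vas_baseline = c(10, 10), vas_post = c(8, 8.5))
  lab <- classify_responders(tab)
  expect_equal(lab$pct_analgesia, c(20, 15))
  expect_equal(lab$responder, c(TRUE, FALSE))

  expect_error(classify_responders(
    data.frame(subject_id = "a", vas_baseline = 0, vas_post = 0)),
    "positive")
})

test_that("adjusted_group_test: reduction to plain t, oracle equivalence,
           null calibration", {
  set.seed(41)
  n <- 24
  grp <- rep(0:1, each = n / 2)

  # covariates orthogonal to group and outcome: group t equals the plain
  # pooled-variance two-sample t
  age <- qr.resid(qr(cbind(1, grp)), rnorm(n))
  gender <- qr.resid(qr(cbind(1, grp, age)), rnorm(n))
  y <- grp * 0.8 + rnorm(n)
  y <- qr.resid(qr(cbind(age, gender)), y)    # strip any covariate share
  got <- adjusted_group_test(y, grp, age, gender)
  plain <- t.test(y[grp == 1], y[grp == 0], var.equal = TRUE)
  # identical group estimate and residual sum of squares; the t statistics
  # differ only through the residual-df factor sqrt((n-2)/(n-4))
  expect_equal(got$estimate, unname(diff(tapply(y, grp, mean))),
               tolerance = 1e-10)
  expect_equal(got$t, unname(plain$statistic) * sqrt((n - 4) / (n - 2)),
               tolerance = 1e-8)

  # worked 12-row table against the normal-equations oracle
  set.seed(42)
  y2 <- rnorm(12); g2 <- rep(0:1, 6); a2 <- rnorm(12, 57, 7)
  s2 <- rbinom(12, 1, 0.5)
  got2 <- adjusted_group_test(y2, g2, a2, s2)
  x <- cbind(1, g2, a2, s2)
  b <- ols_oracle(x, matrix(y2))
  rss <- sum((y2 - x %*% b)^2)
  se <- sqrt(rss / (12 - 4) * solve(t(x) %*% x)[2, 2])
  expect_equal(got2$t, b[2] / se, tolerance = 1e-8)
  expect_equal(got2$F_group, (b[2] / se)^2, tolerance = 1e-8)
  # omnibus F df convention (p, n - p - 1)
  expect_equal(got2$df_model, c(3, 8))

  # zero group effect: p approximately uniform over repetitions
  set.seed(43)
  ps <- vapply(1:200, function(i) {
    yy <- rnorm(16)
    adjusted_group_test(yy, rep(0:1, 8), rnorm(16, 57, 7),
                        rbinom(16, 1, 0.5))$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("jzs_ttest_bf01: no-effect case, monotonicity, quadrature oracle", {
  # t = 0: data favour the null
  expect_gt(jzs_ttest_bf01(t = 0, n1 = 8, n2 = 8)$bf01, 1)
  expect_gt(jzs_ttest_bf01(t = 0, n1 = 50, n2 = 50)$bf01, 1)

  # strictly decreasing in |t| at fixed n
  ts <- seq(0, 5, by = 0.5)
  bfs <- vapply(ts, function(t)
    jzs_ttest_bf01(t = t, n1 = 20, n2 = 20)$bf01, numeric(1))
  expect_true(all(diff(bfs) < 0))

  # n1 = n2 = 20, t = 2.5: equals the brute-force quadrature to 1e-6
  got <- jzs_ttest_bf01(t = 2.5, n1 = 20, n2 = 20)
  expect_equal(got$bf01, 1 / jzs_bf10_oracle(2.5, 20, 20),
               tolerance = 1e-6)
  expect_equal(got$bf10, 1 / got$bf01)

  # data interface and degenerate input
  set.seed(44)
  x <- rnorm(10); y <- rnorm(12) + 1
  got2 <- jzs_ttest_bf01(x, y)
  tval <- unname(t.test(x, y, var.equal = TRUE)$statistic)
  expect_equal(got2$t, tval, tolerance = 1e-10)
  expect_error(jzs_ttest_bf01(rep(1, 5), rep(1, 5)), "pooled variance")
})

test_that("interpret_bf reproduces the evidence bands", {
  expect_equal(interpret_bf(3.29),
               "moderate evidence in favour of the null hypothesis")
  expect_equal(interpret_bf(2.46),
               "anecdotal evidence in favour of the null hypothesis")
  expect_equal(interpret_bf(0.05),
               "strong evidence for an alternative hypothesis")
  expect_equal(interpret_bf(0.2),
               "moderate evidence for an alternative hypothesis")
  expect_equal(interpret_bf(0.5),
               "anecdotal evidence for an alternative hypothesis")
  expect_equal(interpret_bf(25),
               "strong evidence in favour of the null hypothesis")
  # the regularized partition is exhaustive and non-overlapping
  probe <- c(1e-4, 1 / 10, 0.2, 1 / 3, 0.5, 1, 2, 3, 9.99, 10, 1e4)
  expect_true(all(nzchar(vapply(probe, interpret_bf, ""))))
  expect_error(interpret_bf(0), "> 0")
})

test_that("pearson_with_bootstrap: exact case, formula oracle, coverage", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  got <- pearson_with_bootstrap(x, x, n_boot = 100, seed = 1)
  expect_equal(got$r, 1)
  expect_equal(got$ci, c(1, 1))

  # 8-point worked data: r matches the covariance / SD formula
  set.seed(45)
  y <- x + rnorm(8)
  got2 <- pearson_with_bootstrap(x, y, n_boot = 200, seed = 2)
  r_oracle <- mean((x - mean(x)) * (y - mean(y))) /
    (pop_sd_test(x) * pop_sd_test(y))
  expect_equal(got2$r, r_oracle, tolerance = 1e-12)

  # determinism under seed
  expect_identical(got2$ci,
                   pearson_with_bootstrap(x, y, n_boot = 200, seed = 2)$ci)

  # independent x, y: 95% CI covers 0 in about 95% of repetitions
  set.seed(46)
  cover <- vapply(1:100, function(i) {
    xx <- rnorm(25); yy <- rnorm(25)
    ci <- pearson_with_bootstrap(xx, yy, n_boot = 200, seed = i)$ci
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.85)

  expect_error(pearson_with_bootstrap(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("bayes_pearson_bf01: null case, monotonicity, quadrature oracle", {
  expect_gt(bayes_pearson_bf01(r = 0, n = 20)$bf01, 1)

  rs <- seq(0, 0.9, by = 0.1)
  bfs <- vapply(rs, function(r)
    bayes_pearson_bf01(r = r, n = 25)$bf01, numeric(1))
  expect_true(all(diff(bfs) < 0))

  got <- bayes_pearson_bf01(r = 0.5, n = 30)
  expect_equal(got$bf10, pearson_bf10_oracle(0.5, 30), tolerance = 1e-6)

  set.seed(47)
  x <- rnorm(15); y <- 0.6 * x + rnorm(15)
  got2 <- bayes_pearson_bf01(x, y)
  expect_equal(got2$r, cor(x, y), tolerance = 1e-12)
})

test_that("posthoc_simple_effects: null, planted arm effect, Tukey
           monotonicity", {
  set.seed(48)
  n_cell <- 8
  arm <- rep(c("placebo", "duloxetine"), each = 2 * n_cell)
  resp <- rep(rep(c("R", "NR"), each = n_cell), 2)
  age <- rnorm(4 * n_cell, 57, 7); gender <- rbinom(4 * n_cell, 1, 0.5)

  # identical R/NR data within an arm: contrast 0, adjusted p ~ 1
  y0 <- rnorm(4 * n_cell)
  y0[resp == "R" & arm == "placebo"] <- y0[resp == "NR" & arm == "placebo"]
  got0 <- posthoc_simple_effects(y0, arm, resp, age * 0, gender * 0)
  row_p <- got0[got0$arm == "placebo", ]
  expect_equal(row_p$estimate, 0, tolerance = 1e-10)
  expect_gt(row_p$p_tukey, 0.99)

  # planted +delta only in the duloxetine arm: significant only there
  y1 <- rnorm(4 * n_cell, sd = 0.5)
  y1[arm == "duloxetine" & resp == "R"] <-
    y1[arm == "duloxetine" & resp == "R"] + 2.5
  got1 <- posthoc_simple_effects(y1, arm, resp, age, gender)
  expect_lt(got1$p_tukey[got1$arm == "duloxetine"], 0.05)
  expect_gt(got1$p_tukey[got1$arm == "placebo"], 0.05)

  # Tukey-adjusted p >= unadjusted p, always
  for (i in 1:nrow(got1)) expect_gte(got1$p_tukey[i], got1$p[i] - 1e-12)

  expect_error(posthoc_simple_effects(y1[1:5], arm[1:5], resp[1:5],
                                      age[1:5], gender[1:5]),
               "at least 2|two levels")
})

test_that("levene_test: degenerate, oracle, calibration", {
  # two groups with identical values: W = 0
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  got <- levene_test(v, g)
  expect_equal(got$W, 0)
  expect_equal(got$p, 1)

  # worked instance: equals a hand-computed one-way ANOVA on |deviations|
  set.seed(49)
  x <- c(rnorm(10, sd = 1), rnorm(12, sd = 3))
  gg <- rep(c("a", "b"), c(10, 12))
  got2 <- levene_test(x, gg)
  d <- abs(x - ave(x, gg))
  fit <- anova(lm(d ~ gg))
  expect_equal(got2$W, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(got2$p, fit$`Pr(>F)`[1], tolerance = 1e-10)

  # equal variances: p roughly uniform
  set.seed(50)
  ps <- vapply(1:200, function(i)
    levene_test(rnorm(20), rep(c("a", "b"), 10))$p, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

  expect_error(levene_test(1:3, c("a", "a", "b")), "at least 2")
})

test_that("Bayes factor consistency and frequentist/Bayesian direction
           agreement", {
  # fixed true effect: BF01 shrinks with n; true null: BF01 grows
  set.seed(51)
  ns <- c(10, 40, 160)
  bf_eff <- vapply(ns, function(n)
    jzs_ttest_bf01(t = 0.8 * sqrt(n / 2), n1 = n, n2 = n)$bf01, numeric(1))
  expect_true(all(diff(bf_eff) < 0))
  bf_null <- vapply(ns, function(n)
    jzs_ttest_bf01(t = 0, n1 = n, n2 = n)$bf01, numeric(1))
  expect_true(all(diff(bf_null) > 0))

  # strongly separated groups: frequentist direction and BF side agree
  x <- rnorm(20, 2); y <- rnorm(20, 0)
  freq <- adjusted_group_test(c(x, y), rep(c(1, 0), each = 20),
                              rnorm(40, 57, 7), rbinom(40, 1, 0.5))
  bf <- jzs_ttest_bf01(x, y)
  expect_gt(freq$t, 0)
  expect_lt(bf$bf01, 1 / 3)
})
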