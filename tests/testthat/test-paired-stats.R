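# Paired agreement statistics and covariate-adjusted group differences.

test_that("paired t-test matches the hand-computed three-pair case", {
  # d = (1, 2, 3): mean 2, sd 1, t = 2 / (1 / sqrt(3)) = 3.4641
  res <- paired_mean_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$mean_diff, 2)
  expect_equal(res$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-9)

  same <- paired_mean_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  shifted <- paired_mean_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(shifted$degenerate)
  expect_equal(shifted$p_value, 0)
  expect_error(paired_mean_test(1, 2), "at least 2")
})

test_that("paired t-test has nominal type-I error under the null", {
  set.seed(71)
  rej <- mean(replicate(2000, {
    x <- rnorm(25); y <- x + rnorm(25)
    paired_mean_test(x, y)$p_value < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("Pitman-Morgan test is calibrated and detects unequal variance", {
  set.seed(72)
  # equal-variance correlated pairs: rejection near alpha
  rej <- mean(replicate(2000, {
    z <- rnorm(200); x <- z + 0.3 * rnorm(200); y <- z + 0.3 * rnorm(200)
    pitman_variance_test(x, y)$p_value < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)

  # y = 2x + noise: variance ratio 4, high power at n = 100
  rej_pow <- mean(replicate(200, {
    x <- rnorm(100); y <- 2 * x + rnorm(100, sd = 0.5)
    pitman_variance_test(x, y)$p_value < 0.05
  }))
  expect_gt(rej_pow, 0.9)
})

test_that("Pitman statistic is shift-invariant and guards degeneracy", {
  set.seed(73)
  x <- rnorm(50); y <- rnorm(50)
  a <- pitman_variance_test(x, y)
  b <- pitman_variance_test(x + 100, y + 100)
  expect_equal(a$stat, b$stat, tolerance = 1e-12)
  # anti-paired data: x + y constant
  expect_error(pitman_variance_test(x, 5 - x), "zero variance")
  expect_error(pitman_variance_test(x[1:3], y[1:3]), "at least 4")
})

test_that("limits of agreement match the closed form", {
  same <- limits_of_agreement(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$mean_diff, same$lower, same$upper), c(0, 0, 0))

  # d ~ N(0.3, 4.86^2): limits converge to 0.3 -/+ 1.96 * 4.86 = (-9.23, 9.83)
  set.seed(74)
  n <- 2e5
  x <- rnorm(n, 10, 3)
  y <- x - rnorm(n, 0.3, 4.86)
  loa <- limits_of_agreement(x, y)
  expect_equal(loa$lower, 0.3 - 1.96 * 4.86, tolerance = 0.03)
  expect_equal(loa$upper, 0.3 + 1.96 * 4.86, tolerance = 0.03)

  # swapping the conditions flips and swaps the limits
  loa_sw <- limits_of_agreement(y, x)
  expect_equal(loa_sw$lower, -loa$upper, tolerance = 1e-9)
  expect_equal(loa_sw$upper, -loa$lower, tolerance = 1e-9)
})

test_that("McNemar test agrees with the binomial oracle", {
  sym <- mcnemar_paired_proportions(10, 10, method = "chi2")
  expect_equal(sym$stat, 0)
  expect_equal(sym$p_value, 1)

  r <- mcnemar_paired_proportions(15, 5, method = "chi2")
  expect_equal(r$stat, 100 / 20)
  ex <- mcnemar_paired_proportions(15, 5, method = "exact")
  expect_equal(ex$p_value, 2 * pbinom(5, 20, 0.5), tolerance = 1e-12)
  expect_equal(round(ex$p_value, 4), 0.0414)

  # one-sided extreme: 2 * 0.5^40
  far <- mcnemar_paired_proportions(40, 0, method = "exact")
  expect_equal(far$p_value, 2 * 0.5^40, tolerance = 1e-9)

  # no discordant pairs
  expect_error(mcnemar_paired_proportions(0, 0, method = "chi2"), "exact")
  expect_equal(mcnemar_paired_proportions(0, 0, method = "exact")$p_value, 1)

  # continuity-corrected version against the stock implementation
  cc <- mcnemar_paired_proportions(15, 5, method = "chi2_cc")
  ref <- mcnemar.test(matrix(c(30, 15, 5, 50), 2, 2))
  expect_equal(cc$stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cc$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("McNemar exact p is in (0, 1] and 1 when b equals c", {
  for (b in c(0, 3, 10)) {
    p <- mcnemar_paired_proportions(b, b, method = "exact")$p_value
    expect_equal(p, 1)
  }
  for (bc in list(c(5, 1), c(20, 8), c(2, 9))) {
    p <- mcnemar_paired_proportions(bc[1], bc[2], method = "exact")$p_value
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("Cohen's kappa matches the direct formula", {
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a"))$kappa, 1)

  # 60 items: 52 pass/pass, 2 pass/fail, 1 fail/pass, 5 fail/fail
  r1 <- c(rep("pass", 54), rep("fail", 6))
  r2 <- c(rep("pass", 52), rep("fail", 2), "pass", rep("fail", 5))
  k <- cohen_kappa(r1, r2)
  expect_equal(k$observed_agreement, 0.95)
  p_e <- (54 * 53 + 6 * 7) / 60^2
  expect_equal(k$kappa, (0.95 - p_e) / (1 - p_e), tolerance = 1e-12)
  expect_equal(round(k$kappa, 2), 0.74)

  # independent labels: kappa near 0
  set.seed(75)
  a <- sample(c("x", "y"), 10000, replace = TRUE)
  b <- sample(c("x", "y"), 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)$kappa), 0.03)

  # both raters constant: undefined, agreement still reported
  const <- cohen_kappa(rep("p", 5), rep("p", 5))
  expect_true(const$undefined)
  expect_equal(const$observed_agreement, 1)
})

test_that("kappa never exceeds observed agreement when p_e > 0", {
  set.seed(76)
  for (i in 1:20) {
    a <- sample(c("x", "y", "z"), 50, replace = TRUE)
    b <- ifelse(runif(50) < 0.7, a, sample(c("x", "y", "z"), 50, TRUE))
    k <- cohen_kappa(a, b)
    if (!k$undefined) expect_lte(k$kappa, k$observed_agreement)
  }
})

test_that("adjusted difference reduces to the raw mean difference", {
  set.seed(77)
  g <- rep(c(0, 1), each = 30)
  y <- rnorm(60) + 2 * g
  res <- adjusted_group_difference(y, g, n_boot = 200, seed = 3)
  raw <- mean(y[g == 1]) - mean(y[g == 0])
  expect_equal(res$adjusted_diff, raw, tolerance = 1e-12)
  expect_lt(res$ci[1], 2)
  expect_gt(res$ci[2], 1)

  res2 <- adjusted_group_difference(y, g, n_boot = 200, seed = 3)
  expect_identical(res$ci, res2$ci)
})

test_that("adjustment removes confounding and recovers a known shift", {
  set.seed(78)
  n <- 300
  age <- rnorm(n, 70, 5)
  g <- as.numeric(runif(n) < plogis((age - 70) / 3))  # confounded membership
  y <- 0.5 * age + 2 * g + rnorm(n)
  res <- adjusted_group_difference(y, g, covariates = data.frame(age = age),
                                   n_boot = 300, seed = 9)
  expect_lt(abs(res$adjusted_diff - 2), 0.5)
  expect_gt(res$ci[2], res$ci[1])
})

test_that("binary-outcome variant returns a log odds ratio", {
  set.seed(79)
  n <- 400
  g <- rep(c(0, 1), each = n / 2)
  p <- plogis(-0.5 + 1 * g)
  y <- as.numeric(runif(n) < p)
  res <- adjusted_group_difference(y, g, n_boot = 300, seed = 2,
                                   family = "binomial")
  expect_lt(abs(res$adjusted_diff - 1), 0.6)
  expect_equal(res$odds_ratio, exp(res$adjusted_diff))
})

test_that("BCa interval degenerates to the percentile interval when unbiased", {
  # symmetric bootstrap distribution centred on the estimate and symmetric
  # jackknife: z0 = 0 and a = 0, so BCa must equal the percentile interval
  boot_stats <- seq(-1, 1, length.out = 2001)
  est <- 0
  jack <- c(-(1:10), 1:10) / 10
  ci <- serialbsi:::bca_interval(est, boot_stats, jack)
  pct <- unname(quantile(boot_stats, c(0.025, 0.975), type = 7))
  expect_equal(ci, pct, tolerance = 1e-9)
})

test_that("BCa interval agrees with the reference implementation", {
  skip_if_not_installed("boot")
  set.seed(80)
  x <- rexp(60)  # skewed so bias and acceleration are non-trivial
  est <- mean(x)
  nb <- 4000
  boot_stats <- with(list(), {
    set.seed(81)
    replicate(nb, mean(x[sample.int(60, replace = TRUE)]))
  })
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  ours <- serialbsi:::bca_interval(est, boot_stats, jack)
  set.seed(81)
  bo <- boot::boot(x, function(d, i) mean(d[i]), R = nb)
  ref <- boot::boot.ci(bo, type = "bca")$bca[4:5]
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("zero-effect BCa intervals cover zero at the nominal rate", {
  set.seed(82)
  n_rep <- 100
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    g <- rep(c(0, 1), each = 50)
    y <- rnorm(100)
    res <- adjusted_group_difference(y, g, n_boot = 200, seed = 1000 + r)
    cover[r] <- res$ci[1] <= 0 && 0 <= res$ci[2]
  }
  expect_gte(mean(cover), 0.86)
})

test_that("group and design degeneracies are rejected", {
  y <- rnorm(20)
  expect_error(adjusted_group_difference(y, rep(1, 20)), "two levels")
  g <- rep(c(0, 1), each = 10)
  expect_error(
    adjusted_group_difference(y, g, covariates = data.frame(z = g)),
    "inestimable|rank"
  )
})
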