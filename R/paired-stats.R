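# Paired agreement and group-comparison statistics: paired t, Pitman-Morgan,
# Bland-Altman limits of agreement, McNemar, Cohen's kappa, and
# covariate-adjusted group differences with BCa bootstrap intervals.

#' Paired mean comparison (paired t-test)
#'
#' @param x,y Matched numeric vectors (condition A and condition B).
#' @param conf_level Confidence level for the interval.
#' @return A list: `mean_diff`, `ci` (length 2), `p_value`, `t_stat`, `n`,
#'   and `degenerate` (`TRUE` when the differences are exactly constant, in
#'   which case `p_value` is 0 for a nonzero constant and 1 for zero).
#' @export
paired_mean_test <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must be the same length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(mean_diff = md, ci = c(md, md),
                p_value = if (md == 0) 1 else 0,
                t_stat = if (md == 0) 0 else Inf * sign(md),
                n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE, conf.level = conf_level)
  list(mean_diff = unname(tt$estimate), ci = as.numeric(tt$conf.int),
       p_value = tt$p.value, t_stat = unname(tt$statistic), n = n,
       degenerate = FALSE)
}

#' Pitman-Morgan test for equal variances in paired samples
#'
#' Correlates the pairwise sums with the pairwise differences: under equal
#' marginal variances the correlation is zero. The statistic
#' `r * sqrt(n - 2) / sqrt(1 - r^2)` is referred to a t distribution with
#' `n - 2` degrees of freedom (two-sided).
#'
#' @param x,y Matched numeric vectors.
#' @return A list: `stat`, `p_value`, `r`, `n`.
#' @export
pitman_variance_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length")
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  s <- x + y
  d <- x - y
  if (stats::sd(s) == 0 || stats::sd(d) == 0) {
    stop("zero variance of pairwise sums or differences")
  }
  r <- stats::cor(s, d)
  stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(stat = stat, p_value = 2 * stats::pt(-abs(stat), df = n - 2),
       r = r, n = n)
}

#' Bland-Altman limits of agreement
#'
#' @param x,y Matched numeric vectors; the limits are
#'   `mean(d) +/- 1.96 * sd(d)` on the differences `d = x - y`.
#' @return A list: `mean_diff`, `lower`, `upper`, `sd_diff`, `n`.
#' @export
limits_of_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  list(mean_diff = md, lower = md - 1.96 * sdd, upper = md + 1.96 * sdd,
       sd_diff = sdd, n = n)
}

#' McNemar test for paired proportions
#'
#' Takes the 2x2 pass/fail cross-classification of the two conditions as the
#' discordant counts b (pass A / fail B) and c (fail A / pass B). The exact
#' method doubles the smaller binomial tail of `Binomial(b + c, 1/2)` at b,
#' capped at 1; the chi-square method uses `(b - c)^2 / (b + c)` (optionally
#' continuity-corrected) with 1 df.
#'
#' @param b,c Discordant pair counts.
#' @param method `"exact"` (default), `"chi2"`, or `"chi2_cc"`.
#' @return A list: `p_value`, `method`, plus `stat` (chi2 methods) or `b`,
#'   `c` (exact).
#' @export
mcnemar_paired_proportions <- function(b, c, method = c("exact", "chi2", "chi2_cc")) {
  method <- match.arg(method)
  if (b < 0 || c < 0 || b != round(b) || c != round(c)) {
    stop("b and c must be non-negative integers")
  }
  n_disc <- b + c
  if (method == "exact") {
    if (n_disc == 0) return(list(p_value = 1, method = method, b = b, c = c))
    p <- 2 * min(stats::pbinom(min(b, c), n_disc, 0.5),
                 stats::pbinom(max(b, c) - 1, n_disc, 0.5, lower.tail = FALSE))
    return(list(p_value = min(p, 1), method = method, b = b, c = c))
  }
  if (n_disc == 0) {
    stop("no discordant pairs; use method = 'exact' (p = 1)")
  }
  stat <- if (method == "chi2") (b - c)^2 / n_disc else {
    (abs(b - c) - 1)^2 / n_disc
  }
  list(stat = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       method = method, b = b, c = c)
}

#' Cohen's kappa for two raters
#'
#' @param r1,r2 Equal-length label vectors over a shared label set.
#' @return A list: `kappa`, `observed_agreement`, `expected_agreement`, `n`,
#'   and `undefined` (`TRUE` when both raters are constant so chance
#'   agreement is 1 and kappa is undefined).
#' @export
cohen_kappa <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("label vectors must be the same length")
  n <- length(r1)
  if (n < 1) stop("need at least 1 item")
  labels <- sort(unique(c(as.character(r1), as.character(r2))))
  t1 <- table(factor(r1, levels = labels))
  t2 <- table(factor(r2, levels = labels))
  p_o <- mean(as.character(r1) == as.character(r2))
  p_e <- sum(as.numeric(t1) * as.numeric(t2)) / n^2
  if (p_e >= 1) {
    return(list(kappa = NA_real_, observed_agreement = p_o,
                expected_agreement = p_e, n = n, undefined = TRUE))
  }
  list(kappa = (p_o - p_e) / (1 - p_e), observed_agreement = p_o,
       expected_agreement = p_e, n = n, undefined = FALSE)
}

# Bias-corrected and accelerated interval from a bootstrap distribution.
# z0 from the position of the point estimate in the bootstrap distribution,
# acceleration from jackknife skewness; with z0 = a = 0 this reduces to the
# percentile interval.
bca_interval <- function(est, boot_stats, jack_stats, conf_level = 0.95) {
  boot_stats <- boot_stats[is.finite(boot_stats)]
  if (length(boot_stats) < 10) stop("too few finite bootstrap replicates")
  # midrank handling of ties with the estimate keeps z0 = 0 exactly for a
  # symmetric bootstrap distribution centred on the estimate
  prop <- mean(boot_stats < est) + 0.5 * mean(boot_stats == est)
  prop <- min(max(prop, 1 / (length(boot_stats) + 1)),
              length(boot_stats) / (length(boot_stats) + 1))
  z0 <- stats::qnorm(prop)
  jm <- mean(jack_stats)
  num <- sum((jm - jack_stats)^3)
  den <- 6 * (sum((jm - jack_stats)^2))^1.5
  a <- if (den == 0) 0 else num / den
  alpha <- (1 - conf_level) / 2
  zlo <- stats::qnorm(alpha)
  zhi <- stats::qnorm(1 - alpha)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  as.numeric(stats::quantile(boot_stats, c(adj(zlo), adj(zhi)),
                             names = FALSE, type = 7))
}

#' Covariate-adjusted group difference with BCa bootstrap interval
#'
#' The adjusted difference is the group coefficient from a least-squares
#' regression of the outcome on the group indicator plus covariates (for a
#' binary outcome, a logistic regression; the coefficient is then a log odds
#' ratio). The confidence interval is a bias-corrected and accelerated (BCa)
#' bootstrap over subjects.
#'
#' @param outcome Numeric (or 0/1 for `family = "binomial"`) outcome vector.
#' @param group_indicator Two-level vector (factor/character/0-1).
#' @param covariates Optional data frame of adjustment covariates.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed (resampling is deterministic given the seed).
#' @param conf_level Confidence level.
#' @param family `"gaussian"` for a mean difference, `"binomial"` for a log
#'   odds ratio.
#' @return A list: `adjusted_diff`, `ci`, `n`, `n_boot`, `family`, and
#'   `odds_ratio` when `family = "binomial"`.
#' @export
adjusted_group_difference <- function(outcome, group_indicator,
                                      covariates = NULL, n_boot = 2000,
                                      seed = 1L, conf_level = 0.95,
                                      family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  g <- factor(group_indicator)
  if (nlevels(g) != 2) stop("group_indicator must have exactly two levels")
  n <- length(outcome)
  dat <- data.frame(.y = outcome, .g = g)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must match outcome length")
    dat <- cbind(dat, covariates)
    if (n <= ncol(covariates) + 2) stop("too few observations for adjustment")
  }
  fit_coef <- function(d) {
    fit <- if (family == "gaussian") {
      stats::lm(.y ~ ., data = d)
    } else {
      suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
    }
    cf <- stats::coef(fit)
    gname <- grep("^\\.g", names(cf), value = TRUE)
    if (any(is.na(cf)) || length(gname) != 1) {
      stop("group coefficient inestimable (rank-deficient design)")
    }
    unname(cf[gname])
  }
  est <- fit_coef(dat)
  boot_stats <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(fit_coef(dat[idx, , drop = FALSE]), error = function(e) NA_real_)
    }, numeric(1))
  })
  jack_stats <- vapply(seq_len(n), function(i) {
    tryCatch(fit_coef(dat[-i, , drop = FALSE]), error = function(e) NA_real_)
  }, numeric(1))
  jack_stats <- jack_stats[is.finite(jack_stats)]
  ci <- bca_interval(est, boot_stats, jack_stats, conf_level)
  out <- list(adjusted_diff = est, ci = ci, n = n, n_boot = n_boot,
              family = family, seed = as.integer(seed))
  if (family == "binomial") out$odds_ratio <- exp(est)
  out
}
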