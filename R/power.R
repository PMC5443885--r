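# Per-arm sample-size estimation for a trial detecting a proportional
# reduction in atrophy rate, with bootstrap confidence intervals.

#' Specify a sample-size calculation
#'
#' The per-arm sample size for detecting a proportional reduction in the mean
#' annualised atrophy rate is
#' `n = (u + v)^2 * (sigma1^2 + sigma2^2) / (mu1 - mu2)^2`
#' with `mu1 - mu2 = reduction * mu` and `sigma1 = sigma2 = sigma` (treated
#' and placebo SDs assumed equal), rounded up to the next whole subject.
#'
#' `u` and `v` default to the conventional two-decimal normal quantiles 0.84
#' (80% power) and 1.96 (two-sided 5% alpha), which is how such calculations
#' are usually printed; `high_precision = TRUE` recomputes them from `power`
#' and `alpha` at full precision.
#'
#' @param mu Mean annualised atrophy rate in the placebo arm (ml/yr, nonzero).
#' @param sigma SD of the annualised rate (ml/yr, positive).
#' @param reduction Proportional treatment effect in (0, 1], default 0.25.
#' @param power Target power, default 0.80.
#' @param alpha Two-sided significance level, default 0.05.
#' @param u,v Normal quantiles for power and alpha.
#' @param high_precision If `TRUE`, use `qnorm(power)` and
#'   `qnorm(1 - alpha/2)` instead of the two-decimal values.
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(mu, sigma, reduction = 0.25, power = 0.80,
                       alpha = 0.05, u = 0.84, v = 1.96,
                       high_precision = FALSE) {
  if (high_precision) {
    u <- stats::qnorm(power)
    v <- stats::qnorm(1 - alpha / 2)
  }
  if (mu == 0) stop("mu must be nonzero")
  if (sigma <= 0) stop("sigma must be > 0")
  if (reduction <= 0 || reduction > 1) stop("reduction must be in (0, 1]")
  if (abs(round(stats::qnorm(power), 2) - round(u, 2)) > 0.005) {
    stop("u is inconsistent with the requested power")
  }
  if (abs(round(stats::qnorm(1 - alpha / 2), 2) - round(v, 2)) > 0.005) {
    stop("v is inconsistent with the requested alpha")
  }
  structure(list(mu = mu, sigma = sigma, reduction = reduction,
                 power = power, alpha = alpha, u = u, v = v),
            class = "power_spec")
}

#' Per-arm sample size for a proportional rate reduction
#'
#' @param spec A [power_spec()].
#' @return A list: `n_per_arm` (ceiling-rounded integer), `n_raw` (unrounded).
#' @export
sample_size_per_arm <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  n_raw <- (spec$u + spec$v)^2 * 2 * spec$sigma^2 /
    (spec$reduction * spec$mu)^2
  list(n_per_arm = as.integer(ceiling(n_raw)), n_raw = n_raw)
}

#' Bootstrap confidence interval for a sample-size estimate
#'
#' Resamples the per-subject annualised rates with replacement, recomputes
#' the mean, SD and per-arm sample size for each replicate, and reports the
#' percentile interval of the replicate sample sizes around the point
#' estimate computed from the original rates.
#'
#' @param rates Numeric vector of per-subject annualised rates (ml/yr),
#'   length >= 10.
#' @param spec_template A [power_spec()] whose `mu` and `sigma` are replaced
#'   per replicate (its `reduction`, `u`, `v` are reused).
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param conf_level Confidence level.
#' @return A list: `n_per_arm`, `n_raw`, `ci_low`, `ci_high`, `n_dropped`
#'   (replicates with zero mean or zero SD, excluded), `n_boot`.
#' @export
bootstrap_sample_size_ci <- function(rates, spec_template, n_boot = 2000,
                                     seed = 1L, conf_level = 0.95) {
  stopifnot(inherits(spec_template, "power_spec"))
  if (length(rates) < 10) stop("need at least 10 rates")
  if (n_boot < 100) stop("n_boot must be >= 100")
  point <- replicate_n(rates, spec_template)
  if (is.na(point)) stop("rates have zero mean or zero SD")
  ns <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      replicate_n(rates[sample.int(length(rates), replace = TRUE)],
                  spec_template)
    }, numeric(1))
  })
  n_dropped <- sum(is.na(ns))
  if (n_dropped > 0.1 * n_boot) {
    stop("more than 10% of bootstrap replicates degenerate (mu = 0)")
  }
  ns <- ns[!is.na(ns)]
  alpha <- (1 - conf_level) / 2
  ci <- as.numeric(stats::quantile(ns, c(alpha, 1 - alpha),
                                   names = FALSE, type = 1))
  list(n_per_arm = as.integer(ceiling(point)), n_raw = point,
       ci_low = ci[1], ci_high = ci[2], n_dropped = n_dropped,
       n_boot = n_boot)
}

# Per-replicate unrounded sample size; NA when degenerate.
replicate_n <- function(r, spec) {
  mu <- mean(r)
  sigma <- stats::sd(r)
  if (mu == 0 || sigma == 0 || !is.finite(sigma)) return(NA_real_)
  (spec$u + spec$v)^2 * 2 * sigma^2 / (spec$reduction * mu)^2
}

#' Compare sample-size requirements between two protocols
#'
#' Computes per-arm sample sizes from the paired per-subject rate vectors of
#' the two protocols and a paired bootstrap (resampling subjects jointly) of
#' the difference in ceiling-rounded sample sizes.
#'
#' @param rates_a,rates_na Named numeric vectors of per-subject annualised
#'   rates for accelerated and non-accelerated scans; names are subject ids
#'   and must match as sets.
#' @param spec_template A [power_spec()] template (see
#'   [bootstrap_sample_size_ci()]).
#' @param n_boot Number of paired bootstrap resamples.
#' @param seed Integer seed.
#' @param conf_level Confidence level.
#' @return A list: `n_accelerated`, `n_non_accelerated`, `difference`
#'   (non-accelerated minus accelerated), `ci` of the difference.
#' @export
compare_protocol_sample_sizes <- function(rates_a, rates_na, spec_template,
                                          n_boot = 2000, seed = 1L,
                                          conf_level = 0.95) {
  stopifnot(inherits(spec_template, "power_spec"))
  if (is.null(names(rates_a)) || is.null(names(rates_na))) {
    stop("rate vectors must be named by subject id")
  }
  if (!setequal(names(rates_a), names(rates_na))) {
    stop("unmatched subject sets between protocols")
  }
  rates_na <- rates_na[names(rates_a)]
  n <- length(rates_a)
  n_a <- ceiling(replicate_n(rates_a, spec_template))
  n_na <- ceiling(replicate_n(rates_na, spec_template))
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      da <- replicate_n(rates_a[idx], spec_template)
      dn <- replicate_n(rates_na[idx], spec_template)
      if (is.na(da) || is.na(dn)) NA_real_ else ceiling(dn) - ceiling(da)
    }, numeric(1))
  })
  diffs <- diffs[!is.na(diffs)]
  alpha <- (1 - conf_level) / 2
  ci <- as.numeric(stats::quantile(diffs, c(alpha, 1 - alpha),
                                   names = FALSE, type = 1))
  list(n_accelerated = as.integer(n_a), n_non_accelerated = as.integer(n_na),
       difference = as.integer(n_na - n_a), ci = ci)
}
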