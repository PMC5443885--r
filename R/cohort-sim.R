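# Cohort-level simulation: repeated direct-change measures drawn from the
# generative linear mixed model, and paired QC outcomes.

DIAGNOSES <- c("CN", "EMCI", "LMCI", "AD")
SCAN_TYPES <- c("accelerated", "non_accelerated")

#' Specify a simulated longitudinal cohort
#'
#' Defines the generative model for direct change measures: each subject i in
#' diagnostic group dx has a random atrophy-rate deviation
#' `b_i ~ N(0, sigma_b[dx]^2)` and a visit-specific deviation
#' `u_ij ~ N(0, sigma_u^2)` at every visit; the measured change between visits
#' j < k on scan type s is
#' `y = (beta0 + beta1 * s + beta_dx + b_i) * t_jk - u_ij + u_ik + eps`,
#' with `eps ~ N(0, sigma_eps[s]^2)` and `s = 0` for accelerated, `1` for
#' non-accelerated. Both scan types of a visit pair share `b_i` and the
#' `u_ij`, reflecting back-to-back acquisition in the same session.
#'
#' Defaults are at whole-brain scale in ml/year: a control accelerated rate
#' near 5.8, a small protocol offset, increasing rates through EMCI, LMCI and
#' AD, between-subject rate SDs of 3-4, visit-effect SD 1.5 ml and residual
#' SDs of 1 (accelerated) vs 2 (non-accelerated).
#'
#' @param n_per_group Named integer vector of subjects per diagnosis
#'   (CN, EMCI, LMCI, AD).
#' @param visit_times Visit times in years, strictly increasing from 0.
#' @param beta0 Mean control atrophy rate on accelerated scans, ml/yr.
#' @param beta1 Non-accelerated minus accelerated rate offset, ml/yr.
#' @param beta2,beta3,beta4 EMCI, LMCI, AD rate offsets, ml/yr.
#' @param sigma_b Slope SD per diagnosis (length 4, ml/yr).
#' @param sigma_u Visit-effect SD, ml.
#' @param sigma_eps_a,sigma_eps_na Residual SD by scan type, ml.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(CN = 10, EMCI = 10, LMCI = 10, AD = 10),
                        visit_times = c(0, 0.5, 1),
                        beta0 = 5.8, beta1 = 0.04,
                        beta2 = 1.7, beta3 = 5.0, beta4 = 9.1,
                        sigma_b = c(3, 3, 3.5, 4),
                        sigma_u = 1.5,
                        sigma_eps_a = 1, sigma_eps_na = 2,
                        seed = 1L) {
  if (is.null(names(n_per_group))) names(n_per_group) <- DIAGNOSES
  n_per_group <- n_per_group[DIAGNOSES]
  n_per_group[is.na(n_per_group)] <- 0
  names(n_per_group) <- DIAGNOSES
  if (length(visit_times) < 2 || any(diff(visit_times) <= 0) ||
      visit_times[1] != 0) {
    stop("visit_times must be strictly increasing with visit_times[1] = 0")
  }
  if (sum(n_per_group) == 0) stop("n_per_group must include at least one subject")
  sds <- c(sigma_b, sigma_u, sigma_eps_a, sigma_eps_na)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (length(sigma_b) == 1) sigma_b <- rep(sigma_b, 4)
  stopifnot(length(sigma_b) == 4)
  names(sigma_b) <- DIAGNOSES
  structure(list(
    n_per_group = n_per_group, visit_times = as.numeric(visit_times),
    beta = c(beta0 = beta0, beta1 = beta1, beta2 = beta2,
             beta3 = beta3, beta4 = beta4),
    sigma_b = sigma_b, sigma_u = sigma_u,
    sigma_eps = c(accelerated = sigma_eps_a, non_accelerated = sigma_eps_na),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Simulate a table of repeated direct-change measures
#'
#' Draws one record per subject, ordered visit pair and scan type from the
#' generative model of [cohort_spec()].
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with columns `subject_id`, `diagnosis`, `visit_j`,
#'   `visit_k`, `t_years`, `scan_type`, `y_ml`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  vt <- spec$visit_times
  nv <- length(vt)
  pairs <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  dx_offsets <- c(CN = 0, EMCI = unname(spec$beta["beta2"]),
                  LMCI = unname(spec$beta["beta3"]),
                  AD = unname(spec$beta["beta4"]))
  with_seed(spec$seed, {
    rows <- list()
    sid <- 0L
    for (dx in DIAGNOSES) {
      for (i in seq_len(spec$n_per_group[[dx]])) {
        sid <- sid + 1L
        b_i <- stats::rnorm(1, 0, spec$sigma_b[[dx]])
        u <- stats::rnorm(nv, 0, spec$sigma_u)
        for (p in seq_len(nrow(pairs))) {
          j <- pairs[p, "row"]; k <- pairs[p, "col"]
          t_jk <- vt[k] - vt[j]
          for (st in SCAN_TYPES) {
            s01 <- as.numeric(st == "non_accelerated")
            rate <- spec$beta[["beta0"]] + spec$beta[["beta1"]] * s01 +
              dx_offsets[[dx]] + b_i
            eps <- stats::rnorm(1, 0, spec$sigma_eps[[st]])
            rows[[length(rows) + 1L]] <- data.frame(
              subject_id = sprintf("S%04d", sid), diagnosis = dx,
              visit_j = j, visit_k = k, t_years = t_jk,
              scan_type = st, y_ml = rate * t_jk - u[j] + u[k] + eps,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate paired pass/fail quality-control labels
#'
#' Draws correlated within-subject Bernoulli failures for the two scan types
#' with given marginal failure probabilities and a within-pair odds ratio
#' (Plackett construction: the joint cell probabilities are solved from the
#' marginals and the odds ratio, then sampled as a multinomial).
#'
#' @param n Number of subjects.
#' @param p_fail_a,p_fail_na Marginal failure probabilities for accelerated
#'   and non-accelerated scan pairs.
#' @param odds_ratio_dependence Positive within-subject odds ratio; 1 means
#'   independent failures.
#' @param seed Integer seed.
#' @return A data frame with logical columns `fail_accelerated`,
#'   `fail_non_accelerated` and a `subject_id`.
#' @export
simulate_qc_labels <- function(n, p_fail_a, p_fail_na,
                               odds_ratio_dependence = 1, seed = 1L) {
  if (p_fail_a < 0 || p_fail_a > 1 || p_fail_na < 0 || p_fail_na > 1) {
    stop("failure probabilities must lie in [0, 1]")
  }
  if (odds_ratio_dependence <= 0) stop("odds_ratio_dependence must be > 0")
  p1 <- p_fail_a; p2 <- p_fail_na; psi <- odds_ratio_dependence
  if (abs(psi - 1) < 1e-12) {
    p11 <- p1 * p2
  } else {
    s <- 1 + (p1 + p2) * (psi - 1)
    disc <- s^2 - 4 * psi * (psi - 1) * p1 * p2
    if (disc < 0) stop("infeasible marginal/dependence combination")
    p11 <- (s - sqrt(disc)) / (2 * (psi - 1))
  }
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  if (p11 < lo - 1e-9 || p11 > hi + 1e-9) {
    stop("infeasible marginal/dependence combination")
  }
  p11 <- min(max(p11, lo), hi)
  probs <- c(ff = p11, fp = p1 - p11, pf = p2 - p11,
             pp = 1 - p1 - p2 + p11)
  with_seed(seed, {
    cell <- sample(names(probs), n, replace = TRUE, prob = probs)
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      fail_accelerated = cell %in% c("ff", "fp"),
      fail_non_accelerated = cell %in% c("ff", "pf"),
      stringsAsFactors = FALSE
    )
  })
}
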