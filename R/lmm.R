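# Linear mixed model for repeated measures of direct change.
#
# Each record is a measured change y between visits j < k of subject i on one
# scan type. The model is
#   y = (beta0 + beta1*scantype + beta2*EMCI + beta3*LMCI + beta4*AD + b_i) * t
#       - u_ij + u_ik + eps
# with b_i ~ N(0, sigma_b[dx]^2) (diagnosis-specific), u_ij ~ N(0, sigma_u^2)
# per visit, and eps ~ N(0, sigma_eps[scan_type]^2) (optionally common).
# scantype is 0 for accelerated, 1 for non-accelerated, so beta0 is the mean
# control rate on accelerated scans and beta1 the protocol offset.
#
# Estimation is maximum likelihood: the variance parameters are
# log-parametrised and optimised quasi-Newton with beta profiled out by
# generalised least squares at each candidate covariance. Subjects sharing an
# identical design (diagnosis, visit pairs, scan types) share one Cholesky
# factorisation per likelihood evaluation.

validate_change_records <- function(records) {
  need <- c("subject_id", "diagnosis", "visit_j", "visit_k", "t_years",
            "scan_type", "y_ml")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) == 0) stop("no records")
  if (any(records$visit_j >= records$visit_k)) {
    stop("visit_j must be < visit_k for every record")
  }
  if (any(records$t_years <= 0)) stop("t_years must be > 0")
  if (!all(records$scan_type %in% SCAN_TYPES)) {
    stop("scan_type must be one of: ", paste(SCAN_TYPES, collapse = ", "))
  }
  if (!all(records$diagnosis %in% DIAGNOSES)) {
    stop("diagnosis must be one of: ", paste(DIAGNOSES, collapse = ", "))
  }
  key <- paste(records$subject_id, records$scan_type,
               records$visit_j, records$visit_k)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, scan_type, visit_j, visit_k) records")
  }
  ndx <- tapply(records$diagnosis, records$subject_id,
                function(d) length(unique(d)))
  if (any(ndx > 1)) stop("diagnosis must be constant within subject")
  invisible(records)
}

#' Build the mixed-model design for direct change records
#'
#' Fixed-effect rows are `(t, scantype*t, EMCI*t, LMCI*t, AD*t)` (columns for
#' absent diagnoses or a single observed scan type are dropped). The random
#' visit structure is a signed incidence: a record spanning visits j to k
#' loads `-u_ij + u_ik`, so its incidence row has -1 at j and +1 at k and row
#' sums telescope to zero across a visit chain.
#'
#' @param records Data frame of change records (`subject_id`, `diagnosis`,
#'   `visit_j`, `visit_k`, `t_years`, `scan_type`, `y_ml`).
#' @return A list with per-subject design blocks (`subjects`), the fixed
#'   effect column names (`beta_names`), the diagnoses present (`dx_levels`)
#'   and the scan types present.
#' @export
build_change_design <- function(records) {
  validate_change_records(records)
  records <- records[order(records$subject_id, records$scan_type,
                           records$visit_j, records$visit_k), , drop = FALSE]
  dx_present <- DIAGNOSES[DIAGNOSES %in% unique(records$diagnosis)]
  st_present <- SCAN_TYPES[SCAN_TYPES %in% unique(records$scan_type)]
  both_st <- length(st_present) == 2
  beta_names <- c("beta0",
                  if (both_st) "beta1",
                  c(EMCI = "beta2", LMCI = "beta3",
                    AD = "beta4")[setdiff(dx_present, "CN")])
  subjects <- lapply(split(records, records$subject_id), function(r) {
    visits <- sort(unique(c(r$visit_j, r$visit_k)))
    m <- nrow(r)
    W <- matrix(0, m, length(visits))
    W[cbind(seq_len(m), match(r$visit_j, visits))] <- -1
    W[cbind(seq_len(m), match(r$visit_k, visits))] <- 1
    st01 <- as.numeric(r$scan_type == "non_accelerated")
    dx <- r$diagnosis[1]
    X <- cbind(r$t_years,
               if (both_st) st01 * r$t_years,
               vapply(setdiff(dx_present, "CN"), function(d) {
                 as.numeric(dx == d) * r$t_years
               }, numeric(m)))
    colnames(X) <- beta_names
    list(id = r$subject_id[1], dx = dx, X = X, W = W, y = r$y_ml,
         t = r$t_years, st01 = st01,
         key = paste(dx, paste(r$t_years, collapse = ","),
                     paste(st01, collapse = ","),
                     paste(r$visit_j, r$visit_k, collapse = ","), sep = "|"))
  })
  list(subjects = subjects, beta_names = beta_names,
       dx_levels = dx_present, scan_types = st_present)
}

# Group subjects with identical design blocks and stack their outcomes.
group_design <- function(design) {
  keys <- vapply(design$subjects, `[[`, character(1), "key")
  lapply(split(design$subjects, keys), function(subs) {
    s1 <- subs[[1]]
    list(X = s1$X, W = s1$W, t = s1$t, st01 = s1$st01, dx = s1$dx,
         Y = vapply(subs, `[[`, numeric(length(s1$y)), "y"),
         n = length(subs))
  })
}

# theta layout: log sigma_b (one per dx level, or one shared), log sigma_u,
# log sigma_eps (accelerated, non-accelerated; or one shared)
make_negloglik <- function(groups, beta_names, dx_levels,
                           diagnosis_specific_slopes, separate_residuals) {
  n_sb <- if (diagnosis_specific_slopes) length(dx_levels) else 1L
  n_se <- if (separate_residuals) 2L else 1L
  p <- length(beta_names)
  n_total <- sum(vapply(groups, function(g) g$n * length(g$t), numeric(1)))

  eval_fit <- function(theta) {
    sb <- exp(theta[seq_len(n_sb)])
    su <- exp(theta[n_sb + 1L])
    se <- exp(theta[n_sb + 1L + seq_len(n_se)])
    if (n_se == 1L) se <- c(se, se)
    XtX <- matrix(0, p, p)
    Xty <- numeric(p)
    yty <- 0
    ld <- 0
    for (g in groups) {
      sb_g <- if (n_sb == 1L) sb else sb[match(g$dx, dx_levels)]
      V <- sb_g^2 * tcrossprod(g$t) + su^2 * tcrossprod(g$W) +
        diag(se[g$st01 + 1]^2, length(g$t))
      R <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(R)) return(NULL)
      Ym <- if (is.matrix(g$Y)) g$Y else matrix(g$Y, ncol = g$n)
      Xw <- backsolve(R, g$X, transpose = TRUE)
      Yw <- backsolve(R, Ym, transpose = TRUE)
      XtX <- XtX + g$n * crossprod(Xw)
      Xty <- Xty + crossprod(Xw, rowSums(Yw))[, 1]
      yty <- yty + sum(Yw^2)
      ld <- ld + g$n * 2 * sum(log(diag(R)))
    }
    beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    quad <- yty - sum(beta * Xty)
    nll <- 0.5 * (ld + quad + n_total * log(2 * pi))
    list(nll = nll, beta = beta, XtX = XtX)
  }

  list(
    nll = function(theta) {
      f <- eval_fit(theta)
      if (is.null(f) || !is.finite(f$nll)) 1e10 else f$nll
    },
    full = eval_fit,
    n_sb = n_sb, n_se = n_se, n_total = n_total
  )
}

# Method-of-moments style starting values on the log-SD scale.
mom_start <- function(records, n_sb, n_se) {
  rate <- records$y_ml / records$t_years
  subj_mean <- tapply(rate, records$subject_id, mean)
  sb0 <- stats::sd(subj_mean)
  resid <- rate - subj_mean[records$subject_id]
  r0 <- if (length(resid) > 1) stats::sd(resid) else 1
  sb0 <- max(sb0, 0.05, na.rm = TRUE)
  r0 <- max(r0, 0.05, na.rm = TRUE)
  log(c(rep(sb0, n_sb), 0.5 * r0, rep(0.7 * r0, n_se)))
}

#' Fit the direct-change linear mixed model by maximum likelihood
#'
#' Maximises the marginal Gaussian likelihood over the log-parametrised
#' variance components with the fixed effects profiled out by generalised
#' least squares; quasi-Newton optimisation with three starts
#' (method-of-moments, scaled down, scaled up) guards against local optima.
#' Standard errors for the fixed effects come from the inverse GLS information
#' at the optimum.
#'
#' @param records Data frame of change records.
#' @param separate_residuals If `TRUE`, fit scan-type-specific residual
#'   variances; if `FALSE`, a common residual variance.
#' @param diagnosis_specific_slopes If `TRUE`, one random-slope variance per
#'   diagnosis present; if `FALSE`, a single shared slope variance.
#' @param extra_starts Optional list of additional starting vectors on the
#'   log-SD scale.
#' @param reltol Convergence tolerance passed to the optimiser.
#' @return An object of class `change_lmm_fit` with elements `beta`, `se`,
#'   `var_slope`, `var_visit`, `var_resid`, `loglik`, `converged`,
#'   `n_records`, `n_subjects`.
#' @export
fit_change_lmm <- function(records, separate_residuals = TRUE,
                           diagnosis_specific_slopes = TRUE,
                           extra_starts = NULL, reltol = 1e-10) {
  design <- build_change_design(records)
  if (length(design$subjects) < 2) stop("need at least 2 subjects")
  if (length(design$scan_types) < 2) separate_residuals <- FALSE
  groups <- group_design(design)
  obj <- make_negloglik(groups, design$beta_names, design$dx_levels,
                        diagnosis_specific_slopes, separate_residuals)
  start0 <- mom_start(records, obj$n_sb, obj$n_se)
  starts <- c(list(start0, start0 + log(0.3), start0 + log(3)), extra_starts)
  best <- NULL
  conv <- FALSE
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, obj$nll, method = "BFGS",
                   control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    # polish with Nelder-Mead in case BFGS stalled on a numeric-gradient kink
    opt2 <- tryCatch(
      stats::optim(opt$par, obj$nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = reltol)),
      error = function(e) opt
    )
    if (opt2$value < opt$value) opt <- opt2
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      conv <- opt$convergence == 0
    }
  }
  if (is.null(best)) stop("singular covariance: likelihood could not be evaluated")
  f <- obj$full(best$par)
  if (is.null(f)) stop("singular covariance at the optimum")
  vcov_beta <- solve(f$XtX)
  se_beta <- sqrt(diag(vcov_beta))
  sb <- exp(best$par[seq_len(obj$n_sb)])
  su <- exp(best$par[obj$n_sb + 1L])
  se_r <- exp(best$par[obj$n_sb + 1L + seq_len(obj$n_se)])
  if (obj$n_se == 1L) se_r <- c(se_r, se_r)
  var_slope <- stats::setNames(rep(NA_real_, 4), DIAGNOSES)
  if (diagnosis_specific_slopes) {
    var_slope[design$dx_levels] <- sb^2
  } else {
    var_slope[design$dx_levels] <- sb[1]^2
  }
  beta <- stats::setNames(f$beta, design$beta_names)
  structure(list(
    beta = beta, se = stats::setNames(se_beta, design$beta_names),
    vcov_beta = vcov_beta,
    var_slope = var_slope, var_visit = su^2,
    var_resid = c(accelerated = se_r[1]^2, non_accelerated = se_r[2]^2),
    loglik = -best$value, converged = conv,
    separate_residuals = separate_residuals,
    diagnosis_specific_slopes = diagnosis_specific_slopes,
    dx_levels = design$dx_levels, scan_types = design$scan_types,
    theta = best$par,
    n_records = nrow(records),
    n_subjects = length(design$subjects)
  ), class = "change_lmm_fit")
}

#' @export
print.change_lmm_fit <- function(x, ...) {
  cat(sprintf("Direct-change LMM fit (%d records, %d subjects)\n",
              x$n_records, x$n_subjects))
  cat(sprintf("  log-likelihood: %.3f  (converged: %s)\n",
              x$loglik, x$converged))
  tab <- data.frame(estimate = x$beta, se = x$se)
  print(round(tab, 4))
  cat("  slope variance by diagnosis:\n")
  print(round(x$var_slope, 4))
  cat(sprintf("  visit variance: %.4f\n", x$var_visit))
  cat(sprintf("  residual variance: accelerated %.4f, non-accelerated %.4f%s\n",
              x$var_resid[1], x$var_resid[2],
              if (x$separate_residuals) "" else " (common)"))
  invisible(x)
}

#' Likelihood-ratio test for scan-type-specific measurement error
#'
#' Fits the model twice -- once with a common residual variance, once with
#' separate residual variances by scan type -- and refers
#' `2 * (loglik_separate - loglik_common)` to chi-square with 1 df. The
#' common-model optimum is supplied to the separate fit as an extra start so
#' the nesting inequality holds numerically.
#'
#' @param records Data frame of change records with both scan types.
#' @param ... Passed to [fit_change_lmm()].
#' @return A list: `chi2_stat`, `df`, `p_value`, `fit_common`, `fit_separate`.
#' @export
lrt_residual_variances <- function(records, ...) {
  fit_c <- fit_change_lmm(records, separate_residuals = FALSE, ...)
  # start the separate fit from the common optimum (residual SD duplicated)
  th <- fit_c$theta
  start_sep <- c(th[seq_len(length(th) - 1L)], th[length(th)], th[length(th)])
  fit_s <- fit_change_lmm(records, separate_residuals = TRUE,
                          extra_starts = list(start_sep), ...)
  stat <- 2 * (fit_s$loglik - fit_c$loglik)
  if (stat < -1e-4) {
    stop("optimizer failure: separate-residual log-likelihood below common model")
  }
  stat <- max(stat, 0)
  list(chi2_stat = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       fit_common = fit_c, fit_separate = fit_s)
}

#' Model-implied adjusted atrophy rate for a group and scan type
#'
#' Returns the mean annualised rate implied by the fixed effects for the
#' requested diagnosis and scan type (e.g. controls/accelerated is `beta0`,
#' controls/non-accelerated `beta0 + beta1`) with a delta-method standard
#' error from the GLS covariance of the fixed effects.
#'
#' @param fit A `change_lmm_fit`.
#' @param diagnosis One of CN, EMCI, LMCI, AD (must be present in the fit).
#' @param scan_type `"accelerated"` or `"non_accelerated"`.
#' @return A list: `rate`, `se`.
#' @export
adjusted_group_rates <- function(fit, diagnosis,
                                 scan_type = c("accelerated", "non_accelerated")) {
  stopifnot(inherits(fit, "change_lmm_fit"))
  scan_type <- match.arg(scan_type)
  if (!diagnosis %in% fit$dx_levels) {
    stop("diagnosis absent from fit: ", diagnosis)
  }
  cvec <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
  cvec["beta0"] <- 1
  if (scan_type == "non_accelerated" && "beta1" %in% names(cvec)) {
    cvec["beta1"] <- 1
  }
  dx_beta <- c(EMCI = "beta2", LMCI = "beta3", AD = "beta4")
  if (diagnosis != "CN") cvec[dx_beta[[diagnosis]]] <- 1
  rate <- sum(cvec * fit$beta)
  se <- sqrt(drop(t(cvec) %*% fit$vcov_beta %*% cvec))
  list(rate = rate, se = se)
}
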