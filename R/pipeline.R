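# End-to-end synthetic study: simulate -> measure -> fit -> compare -> power,
# with file outputs, a seed manifest and byte-identical reruns.

#' Default configuration for the synthetic study
#'
#' Nested list consumed by [run_synthetic_study()]; serialise with
#' [write_run_config()] / [read_run_config()]. All stage seeds are derived
#' from the single top-level `seed` by fixed offsets, so one integer
#' reproduces the whole study.
#'
#' Cohort generative parameters are scaled per structure to the whole-brain,
#' ventricular and hippocampal annualised-rate regimes (ml/yr).
#'
#' @param seed Master integer seed.
#' @return A nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(grid_shape = c(64L, 64L, 64L), voxel_size = c(1, 1, 1),
                   atrophy_ml = 2, ventricle_growth_ml = 1,
                   hippo_atrophy_ml = 0.05),
    n_phantom_pairs = 3L,
    noise = list(
      accelerated = list(snr_center = 25, snr_gradient = 0.02,
                         noise_model = "rician"),
      non_accelerated = list(snr_center = 25, snr_gradient = 0,
                             noise_model = "rician")
    ),
    motion_severity = list(accelerated = 0, non_accelerated = 0),
    cohort = list(
      brain = list(n_per_group = c(10, 10, 10, 10),  # CN, EMCI, LMCI, AD
                   visit_times = c(0, 0.5, 1),
                   beta0 = 5.8, beta1 = 0.04, beta2 = 1.7, beta3 = 5.0,
                   beta4 = 9.1, sigma_b = c(3, 3, 3.5, 4), sigma_u = 1.5,
                   sigma_eps_a = 1, sigma_eps_na = 2),
      ventricle = list(n_per_group = c(10, 10, 10, 10),
                       visit_times = c(0, 0.5, 1),
                       beta0 = 1.4, beta1 = 0.01, beta2 = 0.35, beta3 = 1.5,
                       beta4 = 2.75, sigma_b = c(1, 1, 1.2, 1.5),
                       sigma_u = 0.3, sigma_eps_a = 0.1, sigma_eps_na = 0.15),
      hippocampus = list(n_per_group = c(10, 10, 10, 10),
                         visit_times = c(0, 0.5, 1),
                         beta0 = 0.07, beta1 = 0.002, beta2 = 0.02,
                         beta3 = 0.07, beta4 = 0.11,
                         sigma_b = c(0.05, 0.05, 0.06, 0.07), sigma_u = 0.02,
                         sigma_eps_a = 0.01, sigma_eps_na = 0.015)
    ),
    qc = list(n = 500L, p_fail_a = 0.07, p_fail_na = 0.14,
              odds_ratio_dependence = 2, rerate_flip_prob = 0.025),
    stats = list(alpha = 0.05, n_boot = 500L),
    power = list(reduction = 0.25, u = 0.84, v = 1.96)
  )
}

#' Write a run configuration to a YAML file
#' @param config Configuration list.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#' @param path YAML path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

# Stage seeds derived from the master seed; offsets keep seeds below 2^31.
stage_seed <- function(config, stage) {
  offsets <- c(phantom = 101L, cohort = 202L, qc = 303L, power = 404L,
               rerate = 505L)
  (config$seed %% 1000000L) * 1000L + offsets[[stage]]
}

cohort_spec_from_config <- function(cfg, seed) {
  cohort_spec(
    n_per_group = unlist(cfg$n_per_group), visit_times = cfg$visit_times,
    beta0 = cfg$beta0, beta1 = cfg$beta1, beta2 = cfg$beta2,
    beta3 = cfg$beta3, beta4 = cfg$beta4, sigma_b = unlist(cfg$sigma_b),
    sigma_u = cfg$sigma_u, sigma_eps_a = cfg$sigma_eps_a,
    sigma_eps_na = cfg$sigma_eps_na, seed = seed
  )
}

# Measure all three structures of one noisy phantom pair.
measure_phantom <- function(ph, noisy_base, noisy_follow) {
  pair <- image_pair(noisy_base, noisy_follow, ph$voxel_volume_ml)
  brain_union <- ph$masks$brain_base | ph$masks$brain_follow
  list(
    brain = kn_bsi(pair, ph$masks$brain_base, ph$masks$brain_follow),
    ventricle = fixed_window_bsi(pair, ph$masks$ventricle_base,
                                 ph$masks$ventricle_follow, brain_union),
    hippocampus = hippo_bsi(pair, ph$masks$hippo_base, ph$masks$hippo_follow,
                            brain_union)
  )
}

#' Simulate a cohort of phantom pairs measured with the BSI
#'
#' The integrated simulate-then-measure loop: each subject gets a true
#' annualised whole-brain atrophy rate drawn from
#' `N(beta0, sigma_b^2)`, a phantom pair realising that loss over `t_years`,
#' scan-type-specific acquisition noise (both scan types share the underlying
#' phantom, emulating back-to-back scanning), and a KN-BSI measurement that
#' becomes the recorded change.
#'
#' @param n_subjects Number of (control) subjects.
#' @param beta0 Mean true atrophy rate, ml/yr.
#' @param sigma_b Between-subject SD of the true rate, ml/yr.
#' @param t_years Interval between the two visits.
#' @param snr Centre SNR for both protocols.
#' @param motion_severity Motion severity applied to the follow-up scans.
#' @param seed Integer seed.
#' @param grid_shape Phantom grid.
#' @return A list: `records` (cohort schema, measured), `truth_rates`.
#' @export
simulate_measured_cohort <- function(n_subjects, beta0 = 5.8, sigma_b = 3,
                                     t_years = 1, snr = 25,
                                     motion_severity = 0, seed = 1L,
                                     grid_shape = c(64L, 64L, 64L)) {
  truth <- with_seed(seed, stats::rnorm(n_subjects, beta0, sigma_b))
  # keep the realised loss inside the brain volume and non-negative
  truth <- pmax(truth, 0)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    ph <- make_phantom_pair(phantom_spec(
      grid_shape = grid_shape, atrophy_ml = truth[i] * t_years,
      seed = seed + i
    ))
    for (st in SCAN_TYPES) {
      ns <- noise_spec(scan_type = st, snr_center = snr,
                       seed = seed * 100L + i * 4L +
                         as.integer(st == "non_accelerated"))
      nb <- add_acquisition_noise(ph$baseline, ns, ph$voxel_size)
      ns2 <- noise_spec(scan_type = st, snr_center = snr,
                        seed = seed * 100L + i * 4L + 2L +
                          as.integer(st == "non_accelerated"))
      nf <- add_acquisition_noise(ph$followup, ns2, ph$voxel_size)
      if (motion_severity > 0) {
        nf <- add_motion_artifact(nf, motion_severity, seed = seed + i)
      }
      res <- kn_bsi(image_pair(nb, nf, ph$voxel_volume_ml),
                    ph$masks$brain_base, ph$masks$brain_follow)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("S%04d", i), diagnosis = "CN",
        visit_j = 1L, visit_k = 2L, t_years = t_years, scan_type = st,
        y_ml = res$value_ml, stringsAsFactors = FALSE
      )
    }
  }
  list(records = do.call(rbind, rows),
       truth_rates = truth)
}

# Annualised per-subject rates from the longest (first-to-last) visit pair.
annualised_rates <- function(records, scan_type) {
  r <- records[records$scan_type == scan_type, , drop = FALSE]
  kmax <- max(r$visit_k)
  r <- r[r$visit_j == 1 & r$visit_k == kmax, , drop = FALSE]
  stats::setNames(r$y_ml / r$t_years, r$subject_id)
}

json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic study
#'
#' Executes simulate -> measure -> fit -> compare -> qc -> power on a
#' configuration, writing phantom NIfTIs, cohort and BSI CSVs, model-fit and
#' statistics reports, a sample-size table, and a manifest recording every
#' seed and a configuration hash. Rerunning with the same configuration
#' reproduces every tabular output byte-identically.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @param out_dir Output directory (created if missing).
#' @param verbose Print one structured log line per stage.
#' @return The study report, invisibly (also written to `out_dir`).
#' @export
run_synthetic_study <- function(config = default_run_config(),
                                out_dir, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- proc.time()["elapsed"]
  log_stage <- function(stage, t0, extra = "") {
    if (verbose) {
      message(sprintf("[serialbsi] stage=%s elapsed=%.1fs %s", stage,
                      proc.time()["elapsed"] - t0, extra))
    }
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  seeds <- list(phantom = stage_seed(config, "phantom"),
                cohort = stage_seed(config, "cohort"),
                qc = stage_seed(config, "qc"),
                power = stage_seed(config, "power"),
                rerate = stage_seed(config, "rerate"))

  # --- stage 1: phantom measurement -----------------------------------------
  t0 <- proc.time()["elapsed"]
  bsi_rows <- list()
  for (s in seq_len(config$n_phantom_pairs)) {
    ph <- make_phantom_pair(phantom_spec(
      grid_shape = unlist(config$phantom$grid_shape),
      voxel_size = unlist(config$phantom$voxel_size),
      atrophy_ml = config$phantom$atrophy_ml,
      ventricle_growth_ml = config$phantom$ventricle_growth_ml,
      hippo_atrophy_ml = config$phantom$hippo_atrophy_ml,
      seed = seeds$phantom + s
    ))
    if (s == 1L) {
      write_volume_nifti(ph$baseline,
                         file.path(out_dir, "phantom_baseline.nii.gz"),
                         ph$voxel_size)
      write_volume_nifti(ph$followup,
                         file.path(out_dir, "phantom_followup.nii.gz"),
                         ph$voxel_size)
      write_volume_nifti(ph$masks$brain_base,
                         file.path(out_dir, "phantom_brain_mask_base.nii.gz"),
                         ph$voxel_size)
      write_volume_nifti(ph$masks$brain_follow,
                         file.path(out_dir, "phantom_brain_mask_follow.nii.gz"),
                         ph$voxel_size)
    }
    for (st in SCAN_TYPES) {
      ncfg <- config$noise[[st]]
      mk_noise <- function(off) noise_spec(
        scan_type = st, snr_center = ncfg$snr_center,
        snr_gradient = ncfg$snr_gradient, noise_model = ncfg$noise_model,
        seed = seeds$phantom + 10L * s + off
      )
      nb <- add_acquisition_noise(ph$baseline, mk_noise(1L), ph$voxel_size)
      nf <- add_acquisition_noise(ph$followup, mk_noise(2L), ph$voxel_size)
      sev <- config$motion_severity[[st]]
      if (sev > 0) nf <- add_motion_artifact(nf, sev, seed = seeds$phantom + s)
      meas <- measure_phantom(ph, nb, nf)
      truth <- c(brain = ph$truth$brain_loss_ml,
                 ventricle = ph$truth$ventricle_growth_ml,
                 hippocampus = ph$truth$hippo_loss_ml)
      for (structure in names(meas)) {
        r <- meas[[structure]]
        w <- r$windows[[1]]
        bsi_rows[[length(bsi_rows) + 1L]] <- data.frame(
          subject_id = sprintf("P%02d", s), structure = structure,
          scan_type = st, visit_j = 1L, visit_k = 2L,
          bsi_ml = r$value_ml, truth_ml = unname(truth[structure]),
          n_boundary_voxels = r$n_boundary_voxels,
          window_lo = w$I1, window_hi = w$I2, stringsAsFactors = FALSE
        )
      }
    }
  }
  bsi_tab <- do.call(rbind, bsi_rows)
  utils::write.csv(bsi_tab, file.path(out_dir, "bsi.csv"), row.names = FALSE)
  log_stage("phantom_bsi", t0, sprintf("pairs=%d", config$n_phantom_pairs))

  # --- stage 2: cohort simulation -------------------------------------------
  t0 <- proc.time()["elapsed"]
  cohorts <- list()
  for (structure in names(config$cohort)) {
    spec <- cohort_spec_from_config(config$cohort[[structure]],
                                    seeds$cohort + match(structure,
                                                         names(config$cohort)))
    cohorts[[structure]] <- simulate_cohort(spec)
    write_cohort_csv(cohorts[[structure]],
                     file.path(out_dir, sprintf("cohort_%s.csv", structure)))
  }
  log_stage("cohort", t0,
            sprintf("structures=%d", length(cohorts)))

  # --- stage 3: mixed-model fits and LRT ------------------------------------
  t0 <- proc.time()["elapsed"]
  fits <- lapply(cohorts, function(rec) {
    lrt <- lrt_residual_variances(rec)
    fit <- lrt$fit_separate
    cn_a <- adjusted_group_rates(fit, "CN", "accelerated")
    cn_na <- adjusted_group_rates(fit, "CN", "non_accelerated")
    list(
      beta = as.list(fit$beta), se = as.list(fit$se),
      var_slope = as.list(fit$var_slope), var_visit = fit$var_visit,
      var_resid = as.list(fit$var_resid), loglik = fit$loglik,
      converged = fit$converged,
      adjusted_rate_cn_accelerated = cn_a$rate,
      adjusted_rate_cn_non_accelerated = cn_na$rate,
      lrt = list(chi2_stat = lrt$chi2_stat, df = lrt$df,
                 p_value = lrt$p_value),
      n_records = fit$n_records, n_subjects = fit$n_subjects
    )
  })
  json_out(fits, file.path(out_dir, "fits.json"))
  log_stage("fit", t0)

  # --- stage 4: paired agreement on the brain cohort ------------------------
  t0 <- proc.time()["elapsed"]
  br <- cohorts$brain
  key <- paste(br$subject_id, br$visit_j, br$visit_k)
  acc <- br[br$scan_type == "accelerated", ]
  nac <- br[br$scan_type == "non_accelerated", ]
  nac <- nac[match(paste(acc$subject_id, acc$visit_j, acc$visit_k),
                   paste(nac$subject_id, nac$visit_j, nac$visit_k)), ]
  paired <- list(
    paired_t = paired_mean_test(nac$y_ml, acc$y_ml),
    pitman = pitman_variance_test(nac$y_ml, acc$y_ml),
    limits_of_agreement = limits_of_agreement(acc$y_ml, nac$y_ml)
  )
  json_out(paired, file.path(out_dir, "paired_stats.json"))
  log_stage("paired_stats", t0, sprintf("pairs=%d", nrow(acc)))

  # --- stage 5: QC comparison -----------------------------------------------
  t0 <- proc.time()["elapsed"]
  qc <- simulate_qc_labels(config$qc$n, config$qc$p_fail_a,
                           config$qc$p_fail_na,
                           config$qc$odds_ratio_dependence, seed = seeds$qc)
  b <- sum(!qc$fail_accelerated & qc$fail_non_accelerated)
  cc <- sum(qc$fail_accelerated & !qc$fail_non_accelerated)
  rerate <- with_seed(seeds$rerate, {
    flip <- stats::runif(nrow(qc)) < config$qc$rerate_flip_prob
    ifelse(flip, !qc$fail_non_accelerated, qc$fail_non_accelerated)
  })
  qc_report <- list(
    n = nrow(qc),
    prop_fail_accelerated = mean(qc$fail_accelerated),
    prop_fail_non_accelerated = mean(qc$fail_non_accelerated),
    mcnemar = mcnemar_paired_proportions(b, cc, method = "exact"),
    rerating_kappa = cohen_kappa(qc$fail_non_accelerated, rerate)
  )
  json_out(qc_report, file.path(out_dir, "qc.json"))
  log_stage("qc", t0)

  # --- stage 6: sample sizes ------------------------------------------------
  t0 <- proc.time()["elapsed"]
  power_rows <- list()
  for (structure in names(cohorts)) {
    rec <- cohorts[[structure]]
    for (dx in c("LMCI", "AD")) {
      sub <- rec[rec$diagnosis == dx, , drop = FALSE]
      if (nrow(sub) == 0) next
      ra <- annualised_rates(sub, "accelerated")
      rna <- annualised_rates(sub, "non_accelerated")
      tmpl <- power_spec(mu = mean(ra), sigma = stats::sd(ra),
                         reduction = config$power$reduction,
                         u = config$power$u, v = config$power$v)
      ba <- bootstrap_sample_size_ci(ra, tmpl, n_boot = config$stats$n_boot,
                                     seed = seeds$power + 1L)
      bna <- bootstrap_sample_size_ci(rna, tmpl, n_boot = config$stats$n_boot,
                                      seed = seeds$power + 2L)
      cmp <- compare_protocol_sample_sizes(ra, rna, tmpl,
                                           n_boot = config$stats$n_boot,
                                           seed = seeds$power + 3L)
      power_rows[[length(power_rows) + 1L]] <- data.frame(
        structure = structure, diagnosis = dx,
        n_accelerated = ba$n_per_arm, ci_lo_a = ba$ci_low,
        ci_hi_a = ba$ci_high,
        n_non_accelerated = bna$n_per_arm, ci_lo_na = bna$ci_low,
        ci_hi_na = bna$ci_high,
        difference = cmp$difference, diff_ci_lo = cmp$ci[1],
        diff_ci_hi = cmp$ci[2], stringsAsFactors = FALSE
      )
    }
  }
  power_tab <- do.call(rbind, power_rows)
  utils::write.csv(power_tab, file.path(out_dir, "sample_size.csv"),
                   row.names = FALSE)
  log_stage("power", t0)

  # --- manifest -------------------------------------------------------------
  outputs <- c("bsi.csv", paste0("cohort_", names(cohorts), ".csv"),
               "fits.json", "paired_stats.json", "qc.json", "sample_size.csv")
  hashes <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(hashes) <- outputs
  manifest <- list(config_hash = config_hash, seeds = seeds,
                   outputs = hashes)
  json_out(manifest, file.path(out_dir, "manifest.json"))
  log_stage("manifest", t_all)

  invisible(list(bsi = bsi_tab, fits = fits, paired = paired, qc = qc_report,
                 sample_size = power_tab, manifest = manifest))
}
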