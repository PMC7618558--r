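# Repeated-simulation study drivers. These are the experiments the analysis
# scripts and the validation suite run: estimator/oracle agreement, null
# calibration, effect recovery under pleiotropy, collider correction,
# colocalization discrimination, pipeline dispatch and checklist behavior,
# and Steiger sensitivity. Replicate counts are arguments so studies can be
# scaled; defaults are the sizes used throughout the package documentation.

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Agreement of the core estimators with independent oracles
#'
#' Draws random instrument sets and small regional pairs and measures the
#' maximum absolute deviation between (a) fixed- and random-effects IVW and
#' a weighted-least-squares fit by `stats::lm`, (b) the weighted median and
#' a brute-force weighted-quantile scan, and (c) colocalization posteriors
#' and exhaustive causal-configuration enumeration.
#'
#' @param seed RNG seed.
#' @param n_sets Random instrument sets for (a) and (b).
#' @param n_regions Random small regions (<= 12 variants) for (c).
#' @return Named list of maximum absolute deviations: `ivw_beta`, `ivw_se`,
#'   `wmedian`, `coloc`.
#' @export
study_oracle_agreement <- function(seed, n_sets = 500L, n_regions = 100L) {
  set.seed(seed)
  d_ivw_beta <- d_ivw_se <- d_wm <- 0
  for (k in seq_len(n_sets)) {
    L <- sample(4:40, 1L)
    h <- data.frame(
      beta_exp = stats::rnorm(L, 0, 0.2) + 0.05 * sample(c(-1, 1), L, TRUE),
      se_exp = stats::runif(L, 0.005, 0.05),
      beta_out = stats::rnorm(L, 0, 0.1),
      se_out = stats::runif(L, 0.01, 0.08)
    )
    w <- 1 / h$se_out^2
    fit <- stats::lm(beta_out ~ beta_exp - 1, data = h, weights = w)
    sm <- summary(fit)
    se_lm <- sm$coefficients[1L, 2L]
    sigma <- sm$sigma
    for (eff in c("fixed", "multiplicative_random")) {
      res <- ivw(h, eff)
      se_ref <- if (eff == "fixed") se_lm / sigma
        else (se_lm / sigma) * max(1, sigma)
      d_ivw_beta <- max(d_ivw_beta, abs(res$beta - stats::coef(fit)[1L]))
      d_ivw_se <- max(d_ivw_se, abs(res$se - se_ref))
    }
    r <- h$beta_out / h$beta_exp
    wq <- h$beta_exp^2 / h$se_out^2
    wm <- weighted_median(h, reps = 100L, seed = k)
    d_wm <- max(d_wm, abs(wm$beta - brute_force_weighted_quantile(r, wq, 0.5)))
  }
  d_coloc <- 0
  for (k in seq_len(n_regions)) {
    J <- sample(2:12, 1L)
    se <- stats::runif(J, 0.01, 0.1)
    rp <- regional_pair(data.frame(
      variant_id = sprintf("v%d", seq_len(J)),
      beta_t1 = stats::rnorm(J, 0, 3 * se), se_t1 = se,
      beta_t2 = stats::rnorm(J, 0, 3 * se), se_t2 = se))
    got <- coloc_posteriors(rp)$pp
    want <- enumerate_coloc_posteriors(rp)
    d_coloc <- max(d_coloc, max(abs(got - want)))
  }
  list(ivw_beta = d_ivw_beta, ivw_se = d_ivw_se, wmedian = d_wm,
       coloc = d_coloc)
}

#' Null calibration of the five estimators
#'
#' Runs the full selection-harmonization-estimation pipeline on replicates
#' simulated under no causal effect (theta = 0) with balanced pleiotropy at
#' the default study conditions, and reports the empirical 95% CI coverage
#' of zero per estimator plus the MR-Egger intercept test's type-I error
#' from a second (cheaper) batch of replicates.
#'
#' @param seed RNG seed.
#' @param reps Replicates for the coverage batch.
#' @param reps_egger Replicates for the intercept type-I batch.
#' @param boot_reps Bootstrap replicates for median/mode SEs.
#' @return List: `coverage` (named numeric per estimator), `egger_type1`,
#'   `summary` (the coverage batch's summary table).
#' @export
study_null_calibration <- function(seed, reps = 1000L, reps_egger = 2000L,
                                   boot_reps = 200L) {
  seeds <- derive_seeds(seed, 2L)
  tr <- sim_truth(theta = 0, n_null_variants = 0L, seed = seeds[1L])
  tab <- recovery_experiment(tr, reps = reps,
                             estimators = c("wald", "ivw", "egger",
                                            "weighted_median",
                                            "weighted_mode"),
                             boot_reps = boot_reps)
  tr2 <- tr
  tr2$seed <- seeds[2L]
  tab2 <- recovery_experiment(tr2, reps = reps_egger, estimators = "egger")
  ip <- attr(tab2, "egger_intercept_pvals")
  list(coverage = stats::setNames(tab$coverage, tab$estimator),
       egger_type1 = mean(ip < 0.05),
       summary = tab)
}

#' Causal-effect recovery under no, directional, and majority-invalid
#' pleiotropy
#'
#' Three experiments at the default study conditions (theta = 0.19, 35
#' instruments, case-control GWAS scales): (1) IVW mean estimate under
#' InSIDE-satisfying balanced pleiotropy; (2) IVW versus MR-Egger mean bias
#' under directional pleiotropy (mean pleiotropic effect 0.02); (3) the
#' weighted median's mean estimate when just under half of the instrument
#' weight is invalid with large directional pleiotropy, in a
#' strong-instrument regime where its breakdown-point behavior is visible.
#'
#' @param seed RNG seed.
#' @param reps_ivw,reps_dir,reps_median Replicates for the three
#'   experiments.
#' @return List: `ivw_mean`, `ivw_bias`, `dir_ivw_bias`, `dir_egger_bias`,
#'   `median_breakdown_mean`, `theta` (the true effect).
#' @export
study_recovery <- function(seed, reps_ivw = 500L, reps_dir = 300L,
                           reps_median = 300L) {
  seeds <- derive_seeds(seed, 3L)
  theta <- 0.19

  tr <- sim_truth(theta = theta, n_null_variants = 0L, seed = seeds[1L])
  tab <- recovery_experiment(tr, reps = reps_ivw, estimators = "ivw")
  ivw_mean <- tab$mean_estimate[1L]

  trd <- sim_truth(theta = theta,
                   pleiotropy = list(mu_alpha = 0.02, sd_alpha = 0.01),
                   n_null_variants = 0L, seed = seeds[2L])
  tabd <- recovery_experiment(trd, reps = reps_dir,
                              estimators = c("ivw", "egger"))
  dir_bias <- stats::setNames(tabd$mean_bias, tabd$estimator)

  # Majority-valid breakdown experiment: 18 valid + 17 invalid instruments
  # of equal weight (beta_exp = 1, shared SEs); the invalid half shares a
  # large positive direct effect. SEs of 0.01 put the per-ratio noise well
  # below the pleiotropic separation so the median's 51%-valid consistency
  # is observable.
  set.seed(seeds[3L])
  L_valid <- 18L; L_invalid <- 17L; L <- L_valid + L_invalid
  est <- numeric(reps_median)
  for (i in seq_len(reps_median)) {
    alpha <- c(rep(0, L_valid), rep(0.5, L_invalid))
    h <- data.frame(
      beta_exp = stats::rnorm(L, 1, 0.01), se_exp = rep(0.01, L),
      beta_out = stats::rnorm(L, theta + alpha, 0.01), se_out = rep(0.01, L)
    )
    r <- h$beta_out / h$beta_exp
    w <- h$beta_exp^2 / h$se_out^2
    est[i] <- weighted_quantile(r, w, 0.5)
  }
  list(theta = theta, ivw_mean = ivw_mean, ivw_bias = ivw_mean - theta,
       dir_ivw_bias = dir_bias[["ivw"]],
       dir_egger_bias = dir_bias[["egger"]],
       median_breakdown_mean = mean(est))
}

#' Collider-slope recovery and downstream bias removal
#'
#' Replicates of the conditional-phenotype scenario (collider slope
#' b = -0.4, 500 incidence variants): the mixture fit's mean recovered
#' slope, and how much of the collider-induced bias in the exposure-to-
#' progression IVW estimate the adjustment removes on average.
#'
#' @param seed RNG seed.
#' @param reps Replicates.
#' @param b True collider slope.
#' @return List: `b_true`, `b_hat_mean`, `raw_mean`, `adjusted_mean`,
#'   `theta`, `bias_removed` (fraction of the raw bias removed).
#' @export
study_collider <- function(seed, reps = 100L, b = -0.4) {
  seeds <- derive_seeds(seed, reps)
  theta <- 0.19
  out <- matrix(NA_real_, reps, 3L,
                dimnames = list(NULL, c("b_hat", "raw", "adj")))
  for (i in seq_len(reps)) {
    tr <- sim_truth(theta = theta, collider = list(b = b), seed = seeds[i])
    sc <- simulate_conditional(tr)
    sh <- slope_hunter_adjust(sc$incidence, sc$progression, seed = seeds[i])
    ins <- select_instruments(maf_filter(sc$exposure, 0.01), sc$ld)
    h_raw <- harmonize_pair(ins$variants, sc$progression)
    h_adj <- harmonize_pair(ins$variants, sh$adjusted)
    out[i, ] <- c(sh$fit$b_hat, ivw(h_raw)$beta, ivw(h_adj)$beta)
  }
  raw_bias <- mean(out[, "raw"]) - theta
  adj_bias <- mean(out[, "adj"]) - theta
  list(b_true = b, b_hat_mean = mean(out[, "b_hat"]),
       raw_mean = mean(out[, "raw"]), adjusted_mean = mean(out[, "adj"]),
       theta = theta,
       bias_removed = 1 - abs(adj_bias) / abs(raw_bias))
}

#' Colocalization discrimination between shared and distinct causal variants
#'
#' Simulates AR(1)-LD regions with a single causal variant per trait —
#' shared or distinct — and reports how often the correct hypothesis clears
#' posterior probability 0.8, plus the worst deviation of the posterior sum
#' from 1.
#'
#' @param seed RNG seed.
#' @param n_regions Regions per condition.
#' @param n_variants,ld_rho,z_causal Region parameters.
#' @return List: `h4_rate_shared`, `h3_rate_distinct`, `max_sum_dev`.
#' @export
study_coloc_discrimination <- function(seed, n_regions = 200L,
                                       n_variants = 200L, ld_rho = 0.9,
                                       z_causal = 8) {
  seeds <- derive_seeds(seed, 2L * n_regions)
  h4 <- h3 <- logical(n_regions)
  sumdev <- 0
  for (i in seq_len(n_regions)) {
    ps <- coloc_posteriors(simulate_region(TRUE, n_variants, ld_rho,
                                           z_causal, seeds[i]))
    h4[i] <- ps$pp[5L] > 0.8
    sumdev <- max(sumdev, abs(sum(ps$pp) - 1))
    pd <- coloc_posteriors(simulate_region(FALSE, n_variants, ld_rho,
                                           z_causal, seeds[n_regions + i]))
    h3[i] <- pd$pp[4L] > 0.8
    sumdev <- max(sumdev, abs(sum(pd$pp) - 1))
  }
  list(h4_rate_shared = mean(h4), h3_rate_distinct = mean(h3),
       max_sum_dev = sumdev)
}

# One full forward analysis on a simulated dataset: primary + sensitivity
# estimators, grid, Steiger, reverse MR, and a collider-corrected MR from a
# matching conditional scenario; assembled into the checklist.
run_checklist_scenario <- function(seed, theta_rev, boot_reps = 200L) {
  seeds <- derive_seeds(seed, 4L)
  tr <- sim_truth(reverse = list(L_rev = 3L, eta_sd = 0.25,
                                 theta_rev = theta_rev),
                  seed = seeds[1L])
  sim <- simulate_pair(tr)
  expo <- maf_filter(sim$exposure, 0.01)
  ins <- select_instruments(expo, sim$ld)
  h <- harmonize_pair(ins$variants, sim$outcome)
  primary <- dispatch_mr(h)
  egger <- mr_egger(h)
  wmed <- weighted_median(h, reps = boot_reps, seed = seeds[2L])
  wmod <- weighted_mode(h, reps = boot_reps, seed = seeds[2L] + 1L)
  grid <- sensitivity_grid(expo, sim$outcome, sim$ld)
  st <- steiger_filter(h)
  st_in <- list(mr = if (nrow(st$harmonized) > 1L) dispatch_mr(st$harmonized)
                else primary,
                n_removed = st$steiger$n_removed)
  rev <- reverse_mr(sim$outcome, sim$exposure, sim$ld)

  trc <- sim_truth(collider = list(b = 0), seed = seeds[3L])
  sc <- simulate_conditional(trc)
  sh <- slope_hunter_adjust(sc$incidence, sc$progression, seed = seeds[4L])
  insc <- select_instruments(maf_filter(sc$exposure, 0.01), sc$ld)
  sh_mr <- dispatch_mr(harmonize_pair(insc$variants, sh$adjusted))

  list(primary = primary,
       checklist = robustness_checklist(primary, egger, wmed, wmod, grid,
                                        slopehunter = sh_mr,
                                        steiger = st_in, reverse = rev),
       reverse = rev)
}

#' Dispatch-rule and robustness-checklist pipeline study
#'
#' Verifies the estimator dispatch rule on harmonized sets of increasing
#' size, evaluates the six-criterion checklist on a consistent synthetic
#' scenario (positive causal effect, balanced pleiotropy, outcome-specific
#' instruments with no reverse effect), and on a matching scenario with a
#' planted reverse-causal pathway that criterion 6 should flag.
#'
#' @param seed RNG seed.
#' @return List: `dispatch_methods` (methods chosen for 1-5 variants),
#'   `dispatch_ok`, `checklist_consistent`, `checklist_reverse`
#'   (checklist data.frames), `n_true_consistent`, `reverse_flagged`.
#' @export
study_pipeline <- function(seed) {
  seeds <- derive_seeds(seed, 3L)
  sim <- simulate_pair(sim_truth(n_null_variants = 0L, seed = seeds[1L]))
  ins <- select_instruments(maf_filter(sim$exposure, 0.01), sim$ld)
  h <- harmonize_pair(ins$variants, sim$outcome)
  methods <- vapply(1:5, function(k) {
    dispatch_mr(h[seq_len(k), , drop = FALSE])$method
  }, character(1L))
  dispatch_ok <- identical(methods,
                           c("wald", "ivw_fixed", "ivw_fixed",
                             "ivw_mre", "ivw_mre"))
  cons <- run_checklist_scenario(seeds[2L], theta_rev = 0)
  revd <- run_checklist_scenario(seeds[3L], theta_rev = 0.3)
  list(dispatch_methods = methods, dispatch_ok = dispatch_ok,
       checklist_consistent = cons$checklist,
       checklist_reverse = revd$checklist,
       n_true_consistent = sum(cons$checklist$status == "pass"),
       reverse_flagged = revd$checklist$status[6L] == "fail")
}

#' Steiger-filter sensitivity to planted reverse-causal variants
#'
#' Simulates instrument panels of 50,000-sample GWAS on both traits where
#' ten planted variants act outcome-first with a true outcome z three times
#' their exposure z, and reports the fraction of planted variants removed
#' (sensitivity) and of genuine forward instruments removed (false
#' removal) by Steiger filtering.
#'
#' @param seed RNG seed.
#' @param reps Replicates.
#' @return List: `sensitivity`, `false_removal`.
#' @export
study_steiger <- function(seed, reps = 200L) {
  seeds <- derive_seeds(seed, reps)
  removed_rev <- kept_counts <- removed_fwd <- fwd_counts <- 0
  for (i in seq_len(reps)) {
    tr <- sim_truth(theta = 0.19,
                    n_exp = c(n_case = 25000, n_control = 25000),
                    n_out = c(n_case = 25000, n_control = 25000),
                    n_null_variants = 0L,
                    reverse = list(L_rev = 10L, eta_sd = 0.5,
                                   theta_rev = 1 / 3),
                    seed = seeds[i])
    sim <- simulate_pair(tr)
    # the simulated panel is the candidate instrument set; Steiger judges
    # directionality regardless of how instruments were selected
    h <- harmonize_pair(sim$exposure, sim$outcome)
    st <- steiger_filter(h)$steiger$table
    is_rev <- st$variant_id %in% sim$truth$reverse_ids
    removed_rev <- removed_rev + sum(!st$keep[is_rev])
    kept_counts <- kept_counts + sum(is_rev)
    removed_fwd <- removed_fwd + sum(!st$keep[!is_rev])
    fwd_counts <- fwd_counts + sum(!is_rev)
  }
  list(sensitivity = removed_rev / kept_counts,
       false_removal = removed_fwd / fwd_counts)
}
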