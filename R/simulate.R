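# Synthetic two-sample GWAS summary statistics with known ground truth.
#
# Summary statistics are simulated directly (no individual-level genotypes):
# true per-variant effects are drawn, per-variant standard errors follow the
# binary-trait approximation se = sqrt(n / (2 maf (1-maf) n_case n_control)),
# and observed effects are truth plus normal noise with those SEs. Null
# variants sit in AR(1) LD blocks; instruments are mutually independent.

#' Ground truth for a synthetic two-sample MR dataset
#'
#' Defaults describe a venous thromboembolism-to-long COVID style analysis:
#' 35 genome-wide significant instruments with log-odds effects drawn at
#' FinnGen scale (21,021 cases / 391,160 controls) against an outcome GWAS
#' of 3,018 cases / 994,582 controls, causal log-odds effect 0.19
#' (= log 1.21), balanced pleiotropy, and AR(1) LD within null blocks.
#'
#' @param theta True causal log-odds effect of exposure on outcome.
#' @param L Number of true instruments.
#' @param maf_range Interval for simulated minor allele frequencies,
#'   within (0, 0.5].
#' @param gamma_sd SD of true instrument effects on the exposure; effects too
#'   small to clear genome-wide significance (plus a 2-SE margin) are
#'   redrawn so L is attained.
#' @param pleiotropy List `mu_alpha` (mean direct outcome effect in the
#'   exposure-increasing allele orientation; nonzero = directional
#'   pleiotropy), `sd_alpha`, and `cor_gamma` (correlation of pleiotropic
#'   with instrument effects; 0 satisfies InSIDE).
#' @param n_exp,n_out Named vectors `c(n_case =, n_control =)` for the two
#'   binary-trait GWAS.
#' @param ld_rho AR(1) LD correlation within null-variant blocks.
#' @param n_null_variants Background null variants (blocks of 10).
#' @param overlap_rho Correlation between the exposure and outcome sampling
#'   noise (sample-overlap emulation); default 0.
#' @param reverse Optional list `L_rev`, `eta_sd`, `theta_rev` planting
#'   outcome-specific instruments whose effects leak back onto the exposure
#'   with slope `theta_rev` (a true reverse-causal pathway).
#' @param collider Optional list for [simulate_conditional()]: `b` (collider
#'   slope), `kappa` (exposure effect on the index event), `delta_sd`,
#'   `n_incidence`, `prop_prog`, `prog_sd`, `n_inc` (incidence GWAS
#'   case/control sizes).
#' @param seed Mandatory RNG seed.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(theta = 0.19, L = 35L,
                      maf_range = c(0.05, 0.5),
                      gamma_sd = 0.12,
                      pleiotropy = list(mu_alpha = 0, sd_alpha = 0.01,
                                        cor_gamma = 0),
                      n_exp = c(n_case = 21021, n_control = 391160),
                      n_out = c(n_case = 3018, n_control = 994582),
                      ld_rho = 0.9, n_null_variants = 200L,
                      overlap_rho = 0,
                      reverse = NULL, collider = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (L < 1L) stop("L must be >= 1")
  if (!(maf_range[1L] > 0 && maf_range[2L] <= 0.5 &&
        maf_range[1L] <= maf_range[2L])) {
    stop("maf_range must lie within (0, 0.5]")
  }
  pl <- utils::modifyList(list(mu_alpha = 0, sd_alpha = 0.01, cor_gamma = 0),
                          as.list(pleiotropy))
  structure(list(theta = theta, L = as.integer(L), maf_range = maf_range,
                 gamma_sd = gamma_sd, pleiotropy = pl,
                 n_exp = n_exp, n_out = n_out, ld_rho = ld_rho,
                 n_null_variants = as.integer(n_null_variants),
                 overlap_rho = overlap_rho,
                 reverse = reverse, collider = collider,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

# Binary-trait SE approximation given maf and case/control counts.
binary_se <- function(maf, n_case, n_control) {
  n <- n_case + n_control
  sqrt(n / (2 * maf * (1 - maf) * n_case * n_control))
}

ar1_matrix <- function(k, rho) rho^abs(outer(seq_len(k), seq_len(k), "-"))

# Draw effects with |gamma| large enough that the observed exposure z clears
# genome-wide significance with a 2-SE margin (keeps L fixed without
# winner's-curse selection on the noise).
draw_significant_effects <- function(L, sd, se, z_needed) {
  g <- stats::rnorm(L, 0, sd)
  for (round in 1:1000) {
    small <- abs(g) < z_needed * se
    if (!any(small)) return(g)
    g[small] <- stats::rnorm(sum(small), 0, sd)
  }
  stop("infeasible configuration: instrument effects cannot clear the ",
       "significance tier; increase sample size or gamma_sd")
}

make_assoc_df <- function(id, chrom, pos, eaf, beta, se, n_case, n_control) {
  data.frame(variant_id = id, chrom = as.character(chrom), pos = pos,
             effect_allele = "A", other_allele = "G",
             eaf = eaf, beta = beta, se = se,
             # floor at the smallest normal double: |z| > ~38 underflows,
             # and p = 0 would (rightly) fail record validation on re-read
             pval = pmax(two_sided_p(beta / se), .Machine$double.xmin),
             n = n_case + n_control, n_case = n_case, n_control = n_control,
             stringsAsFactors = FALSE)
}

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' Instruments receive exposure effects `gamma ~ N(0, gamma_sd^2)` (redrawn
#' until genome-wide significant at the exposure scale), pleiotropic direct
#' outcome effects `alpha`, and outcome effects `theta * gamma + alpha`.
#' Optional reverse instruments affect the outcome directly and the exposure
#' via `theta_rev`. Null variants (true effect zero) fill AR(1) LD blocks of
#' ten; their sampling noise is correlated according to the block LD, and
#' exposure/outcome noise can be correlated to emulate sample overlap.
#'
#' @param truth A [sim_truth()].
#' @return List of class `sim_output`: `exposure`, `outcome` (variant
#'   association data.frames), `ld` (an `ld_matrix`), `truth` (the input,
#'   plus drawn `gamma`, `alpha` and variant roles).
#' @export
simulate_pair <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(truth$seed)
  z_gws <- stats::qnorm(2.5e-8, lower.tail = FALSE)
  L <- truth$L
  Lr <- if (is.null(truth$reverse)) 0L else as.integer(truth$reverse$L_rev)
  n_null <- truth$n_null_variants
  block <- 10L
  n_tot <- L + Lr + n_null

  maf <- stats::runif(n_tot, truth$maf_range[1L], truth$maf_range[2L])
  se_exp <- binary_se(maf, truth$n_exp[["n_case"]], truth$n_exp[["n_control"]])
  se_out <- binary_se(maf, truth$n_out[["n_case"]], truth$n_out[["n_control"]])

  idx_ins <- seq_len(L)
  idx_rev <- if (Lr) L + seq_len(Lr) else integer(0)
  idx_null <- if (n_null) L + Lr + seq_len(n_null) else integer(0)

  gamma <- draw_significant_effects(L, truth$gamma_sd, se_exp[idx_ins],
                                    z_gws + 2)
  # mu_alpha is the mean pleiotropic effect in the exposure-increasing
  # allele orientation (sign(gamma)); cor_gamma > 0 couples the remaining
  # pleiotropy to instrument strength (an InSIDE violation).
  pl <- truth$pleiotropy
  alpha <- pl$mu_alpha * sign(gamma) +
    pl$cor_gamma * (pl$sd_alpha / truth$gamma_sd) * gamma +
    sqrt(max(0, 1 - pl$cor_gamma^2)) * stats::rnorm(L, 0, pl$sd_alpha)

  beta_exp_true <- numeric(n_tot)
  beta_out_true <- numeric(n_tot)
  beta_exp_true[idx_ins] <- gamma
  beta_out_true[idx_ins] <- truth$theta * gamma + alpha
  eta <- numeric(0)
  if (Lr) {
    eta <- draw_significant_effects(Lr, truth$reverse$eta_sd,
                                    se_out[idx_rev], z_gws + 2)
    beta_out_true[idx_rev] <- eta
    beta_exp_true[idx_rev] <- truth$reverse$theta_rev * eta
  }

  # Placement: instruments and reverse instruments each isolated (cycling
  # chromosomes, 20 Mb apart); null variants in 10-variant AR(1) blocks.
  chrom <- character(n_tot)
  pos <- numeric(n_tot)
  solo <- c(idx_ins, idx_rev)
  chrom[solo] <- as.character(((seq_along(solo) - 1L) %% 22L) + 1L)
  pos[solo] <- 1e6 + ((seq_along(solo) - 1L) %/% 22L) * 2e7
  if (n_null) {
    nb <- ceiling(n_null / block)
    bid <- rep(seq_len(nb), each = block)[seq_len(n_null)]
    within <- (seq_len(n_null) - 1L) %% block
    chrom[idx_null] <- as.character(((bid - 1L) %% 22L) + 1L)
    pos[idx_null] <- 1e8 + ((bid - 1L) %/% 22L) * 5e7 + within * 5e3
  }

  # Sampling noise: AR(1)-correlated within null blocks; exposure/outcome
  # noise correlated by overlap_rho.
  z_e <- stats::rnorm(n_tot)
  z_o_ind <- stats::rnorm(n_tot)
  if (n_null) {
    ch <- chol(ar1_matrix(block, truth$ld_rho))
    nb <- ceiling(n_null / block)
    corr_block <- function(z) {
      full <- ceiling(length(z) / block) * block
      zz <- c(z, stats::rnorm(full - length(z)))
      m <- matrix(zz, nrow = block)
      as.vector(crossprod(ch, m))[seq_along(z)]
    }
    z_e[idx_null] <- corr_block(stats::rnorm(n_null))
    z_o_ind[idx_null] <- corr_block(stats::rnorm(n_null))
  }
  rho <- truth$overlap_rho
  z_o <- rho * z_e + sqrt(1 - rho^2) * z_o_ind

  ids <- sprintf("rs%06d", seq_len(n_tot))
  exposure <- make_assoc_df(ids, chrom, pos, maf,
                            beta_exp_true + se_exp * z_e, se_exp,
                            truth$n_exp[["n_case"]], truth$n_exp[["n_control"]])
  outcome <- make_assoc_df(ids, chrom, pos, maf,
                           beta_out_true + se_out * z_o, se_out,
                           truth$n_out[["n_case"]], truth$n_out[["n_control"]])

  r <- diag(n_tot)
  if (n_null) {
    ar <- ar1_matrix(block, truth$ld_rho)
    for (b in seq_len(ceiling(n_null / block))) {
      sel <- idx_null[bid == b]
      k <- length(sel)
      r[sel, sel] <- ar[seq_len(k), seq_len(k)]
    }
  }
  ld <- ld_matrix(ids, r)

  truth_echo <- truth
  truth_echo$gamma <- gamma
  truth_echo$alpha <- alpha
  truth_echo$eta <- eta
  truth_echo$instrument_ids <- ids[idx_ins]
  truth_echo$reverse_ids <- ids[idx_rev]
  structure(list(exposure = exposure, outcome = outcome, ld = ld,
                 truth = truth_echo),
            class = "sim_output")
}

#' Simulate incidence and conditional-progression GWAS with collider bias
#'
#' Emulates a progression phenotype ascertained conditional on an index
#' event: the observed progression effect of every variant is its true
#' progression effect plus `b` times its incidence effect. The panel holds
#' the exposure instruments (whose incidence effects are `kappa * gamma`),
#' `n_incidence` incidence-associated variants — a fraction `prop_prog` of
#' which also carry true progression effects (the free mixture component),
#' the rest incidence-only — plus sampling noise at each GWAS's scale.
#'
#' @param truth A [sim_truth()] with `collider` set (fields `b`, `kappa`,
#'   `delta_sd`, `n_incidence`, `prop_prog`, `prog_sd`, `n_inc`).
#' @return List of class `sim_output_conditional`: `exposure`, `incidence`,
#'   `progression` association data.frames, `ld` (identity), `truth`.
#' @export
simulate_conditional <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  co <- truth$collider
  if (is.null(co) || !is.finite(co$b)) stop("truth$collider$b must be set")
  co <- utils::modifyList(
    list(b = -0.4, kappa = 0.3, delta_sd = 0.1, n_incidence = 500L,
         prop_prog = 0.15, prog_sd = 0.05,
         n_inc = c(n_case = 122616, n_control = 2475240)), as.list(co))
  set.seed(truth$seed)
  z_gws <- stats::qnorm(2.5e-8, lower.tail = FALSE)
  L <- truth$L
  M <- as.integer(co$n_incidence)
  n_tot <- L + M

  maf <- stats::runif(n_tot, truth$maf_range[1L], truth$maf_range[2L])
  se_exp <- binary_se(maf, truth$n_exp[["n_case"]], truth$n_exp[["n_control"]])
  se_inc <- binary_se(maf, co$n_inc[["n_case"]], co$n_inc[["n_control"]])
  se_pro <- binary_se(maf, truth$n_out[["n_case"]], truth$n_out[["n_control"]])

  idx_ins <- seq_len(L)
  idx_inc <- L + seq_len(M)
  gamma <- draw_significant_effects(L, truth$gamma_sd, se_exp[idx_ins],
                                    z_gws + 2)
  delta <- numeric(n_tot)
  delta[idx_ins] <- co$kappa * gamma
  delta[idx_inc] <- draw_significant_effects(M, co$delta_sd, se_inc[idx_inc],
                                             z_gws + 2)
  prog_true <- numeric(n_tot)
  prog_true[idx_ins] <- truth$theta * gamma
  n_c2 <- round(co$prop_prog * M)
  idx_c2 <- idx_inc[seq_len(n_c2)]
  prog_true[idx_c2] <- stats::rnorm(n_c2, 0, co$prog_sd)

  beta_exp_true <- numeric(n_tot)
  beta_exp_true[idx_ins] <- gamma
  prog_obs_mean <- prog_true + co$b * delta

  ids <- sprintf("rs%06d", seq_len(n_tot))
  chrom <- as.character(((seq_len(n_tot) - 1L) %% 22L) + 1L)
  pos <- 1e6 + ((seq_len(n_tot) - 1L) %/% 22L) * 2e7
  exposure <- make_assoc_df(ids, chrom, pos, maf,
                            beta_exp_true + se_exp * stats::rnorm(n_tot),
                            se_exp, truth$n_exp[["n_case"]],
                            truth$n_exp[["n_control"]])
  incidence <- make_assoc_df(ids, chrom, pos, maf,
                             delta + se_inc * stats::rnorm(n_tot), se_inc,
                             co$n_inc[["n_case"]], co$n_inc[["n_control"]])
  progression <- make_assoc_df(ids, chrom, pos, maf,
                               prog_obs_mean + se_pro * stats::rnorm(n_tot),
                               se_pro, truth$n_out[["n_case"]],
                               truth$n_out[["n_control"]])
  truth_echo <- truth
  truth_echo$collider <- co
  truth_echo$gamma <- gamma
  truth_echo$delta <- delta
  truth_echo$prog_true <- prog_true
  truth_echo$instrument_ids <- ids[idx_ins]
  truth_echo$incidence_only_ids <- ids[setdiff(idx_inc, idx_c2)]
  structure(list(exposure = exposure, incidence = incidence,
                 progression = progression,
                 ld = ld_matrix(ids, diag(n_tot)), truth = truth_echo),
            class = "sim_output_conditional")
}

#' Simulate a regional association pair for colocalization
#'
#' One causal variant per trait (the same index when `shared`, distinct
#' weakly-linked indices otherwise) in an AR(1) LD region; marginal z-scores
#' are `r * z_causal` plus LD-correlated standard-normal noise, and effects
#' are back-computed at a uniform per-variant standard error
#' `1/sqrt(n_region)`.
#'
#' @param shared Logical: do the two traits share the causal variant?
#' @param n_variants Region size (>= 2).
#' @param ld_rho AR(1) LD correlation between adjacent variants.
#' @param z_causal Causal-variant z-score magnitude (per trait).
#' @param seed RNG seed.
#' @param n_region Nominal GWAS sample size fixing the uniform SE.
#' @return A [regional_pair()] with attribute `causal_idx` (length-2).
#' @export
simulate_region <- function(shared, n_variants, ld_rho, z_causal, seed,
                            n_region = 10000) {
  if (n_variants < 2L) stop("n_variants must be >= 2")
  set.seed(seed)
  R <- ar1_matrix(n_variants, ld_rho)
  ch <- chol(R)
  i1 <- max(1L, round(n_variants / 4))
  i2 <- if (shared) i1 else min(n_variants, round(3 * n_variants / 4))
  z1 <- R[, i1] * z_causal + drop(crossprod(ch, stats::rnorm(n_variants)))
  z2 <- R[, i2] * z_causal + drop(crossprod(ch, stats::rnorm(n_variants)))
  se <- rep(1 / sqrt(n_region), n_variants)
  out <- regional_pair(data.frame(
    variant_id = sprintf("rv%05d", seq_len(n_variants)),
    beta_t1 = z1 * se, se_t1 = se,
    beta_t2 = z2 * se, se_t2 = se,
    stringsAsFactors = FALSE))
  attr(out, "causal_idx") <- c(i1, i2)
  out
}

#' Simulate a two-exposure mediation trio for multivariable MR
#'
#' Exposure 1 instruments carry effects `gamma1`; exposure 2 instruments
#' carry `gamma2`; exposure 1 affects exposure 2 with slope `kappa12`
#' (mediation path), and the outcome is
#' `theta_direct * (exposure 1) + theta_exp2 * (exposure 2)`, so exposure 1's
#' total (univariable) effect is `theta_direct + theta_exp2 * kappa12` while
#' its direct effect is `theta_direct`.
#'
#' @param theta_direct Direct effect of exposure 1 on the outcome.
#' @param theta_exp2 Effect of exposure 2 on the outcome.
#' @param kappa12 Effect of exposure 1 on exposure 2.
#' @param L1,L2 Instrument counts for the two exposures.
#' @param gamma_sd SD of true instrument effects (both exposures).
#' @param n_exp1,n_exp2,n_out Case/control sizes for the three GWAS.
#' @param maf_range MAF interval.
#' @param seed RNG seed.
#' @return List of class `sim_output_mv`: `exp1`, `exp2`, `outcome`
#'   association data.frames, `ld` (identity), `truth` list.
#' @export
simulate_mv <- function(theta_direct = 0.15, theta_exp2 = 0.2, kappa12 = 0.3,
                        L1 = 35L, L2 = 25L, gamma_sd = 0.12,
                        n_exp1 = c(n_case = 21021, n_control = 391160),
                        n_exp2 = c(n_case = 32519, n_control = 2062805),
                        n_out = c(n_case = 3018, n_control = 994582),
                        maf_range = c(0.05, 0.5), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  z_gws <- stats::qnorm(2.5e-8, lower.tail = FALSE)
  n_tot <- L1 + L2
  maf <- stats::runif(n_tot, maf_range[1L], maf_range[2L])
  se1 <- binary_se(maf, n_exp1[["n_case"]], n_exp1[["n_control"]])
  se2 <- binary_se(maf, n_exp2[["n_case"]], n_exp2[["n_control"]])
  seo <- binary_se(maf, n_out[["n_case"]], n_out[["n_control"]])
  i1 <- seq_len(L1); i2 <- L1 + seq_len(L2)
  g1 <- draw_significant_effects(L1, gamma_sd, se1[i1], z_gws + 2)
  g2 <- draw_significant_effects(L2, gamma_sd, se2[i2], z_gws + 2)
  b_exp1 <- numeric(n_tot); b_exp1[i1] <- g1
  b_exp2 <- numeric(n_tot); b_exp2[i2] <- g2
  b_exp2 <- b_exp2 + kappa12 * b_exp1
  b_out <- theta_direct * b_exp1 + theta_exp2 * b_exp2

  ids <- sprintf("rs%06d", seq_len(n_tot))
  chrom <- as.character(((seq_len(n_tot) - 1L) %% 22L) + 1L)
  pos <- 1e6 + ((seq_len(n_tot) - 1L) %/% 22L) * 2e7
  exp1 <- make_assoc_df(ids, chrom, pos, maf,
                        b_exp1 + se1 * stats::rnorm(n_tot), se1,
                        n_exp1[["n_case"]], n_exp1[["n_control"]])
  exp2 <- make_assoc_df(ids, chrom, pos, maf,
                        b_exp2 + se2 * stats::rnorm(n_tot), se2,
                        n_exp2[["n_case"]], n_exp2[["n_control"]])
  outc <- make_assoc_df(ids, chrom, pos, maf,
                        b_out + seo * stats::rnorm(n_tot), seo,
                        n_out[["n_case"]], n_out[["n_control"]])
  structure(list(exp1 = exp1, exp2 = exp2, outcome = outc,
                 ld = ld_matrix(ids, diag(n_tot)),
                 truth = list(theta_direct = theta_direct,
                              theta_exp2 = theta_exp2, kappa12 = kappa12,
                              gamma1 = g1, gamma2 = g2, seed = seed)),
            class = "sim_output_mv")
}

run_estimator <- function(h, name, boot_reps, seed) {
  switch(name,
         wald = wald_ratio(h[1L, , drop = FALSE]),
         ivw = ivw(h, "multiplicative_random"),
         ivw_fixed = ivw(h, "fixed"),
         dispatch = dispatch_mr(h),
         egger = mr_egger(h),
         weighted_median = weighted_median(h, reps = boot_reps, seed = seed),
         weighted_mode = weighted_mode(h, reps = boot_reps, seed = seed),
         stop("unknown estimator: ", name))
}

#' Repeated-simulation recovery and calibration experiment
#'
#' Repeatedly simulates a summary-statistics pair from `truth`, runs the full
#' selection pipeline (MAF filter, significance threshold, LD clumping,
#' harmonization) and the requested estimators, and summarizes bias, RMSE,
#' empirical 95% CI coverage of the true effect and mean CI width.
#'
#' @param truth A [sim_truth()]; per-replicate seeds are derived from
#'   `truth$seed`.
#' @param reps Number of replicates.
#' @param estimators Subset of `c("wald", "ivw", "ivw_fixed", "dispatch",
#'   "egger", "weighted_median", "weighted_mode")`.
#' @param boot_reps Bootstrap replicates for median/mode SEs.
#' @param p_threshold,r2_threshold,maf_min Selection parameters.
#' @param path Optional TSV path for the summary table.
#' @return data.frame with one row per estimator: `estimator, reps,
#'   mean_estimate, mean_bias, rmse, coverage, mean_ci_width`, with the
#'   per-replicate estimates in attribute `estimates`.
#' @export
recovery_experiment <- function(truth, reps,
                                estimators = c("ivw", "egger",
                                               "weighted_median",
                                               "weighted_mode"),
                                boot_reps = 200L, p_threshold = 5e-8,
                                r2_threshold = 1e-3, maf_min = 0.01,
                                path = NULL) {
  set.seed(truth$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, reps + length(estimators))
  est <- array(NA_real_, dim = c(reps, length(estimators), 3L),
               dimnames = list(NULL, estimators, c("beta", "lo", "hi")))
  intercept_p <- rep(NA_real_, reps)
  for (i in seq_len(reps)) {
    tr <- truth
    tr$seed <- seeds[i]
    sim <- simulate_pair(tr)
    expo <- maf_filter(sim$exposure, maf_min)
    ins <- select_instruments(expo, sim$ld, p_threshold, r2_threshold)
    h <- harmonize_pair(ins$variants, sim$outcome)
    for (j in seq_along(estimators)) {
      res <- run_estimator(h, estimators[j], boot_reps,
                           seed = seeds[reps + j] + i)
      est[i, j, ] <- c(res$beta, res$ci_low, res$ci_high)
      if (estimators[j] == "egger") intercept_p[i] <- res$egger_intercept_pval
    }
  }
  theta <- truth$theta
  out <- do.call(rbind, lapply(seq_along(estimators), function(j) {
    b <- est[, j, "beta"]
    data.frame(estimator = estimators[j], reps = reps,
               mean_estimate = mean(b), mean_bias = mean(b) - theta,
               rmse = sqrt(mean((b - theta)^2)),
               coverage = mean(est[, j, "lo"] <= theta &
                                 theta <= est[, j, "hi"]),
               mean_ci_width = mean(est[, j, "hi"] - est[, j, "lo"]),
               stringsAsFactors = FALSE)
  }))
  attr(out, "estimates") <- est
  attr(out, "egger_intercept_pvals") <- intercept_p
  if (!is.null(path)) write_results(out, path, "tsv")
  out
}
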