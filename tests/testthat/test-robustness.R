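# Sensitivity grid, robustness checklist, specificity and reverse MR.

mk_res <- function(beta, se, intercept_p = NA_real_) {
  r <- mrforge:::make_mr_result("ivw_mre", 10L, beta, se)
  r$egger_intercept_pval <- intercept_p
  r
}

test_that("a single-cell grid equals a direct dispatch call", {
  sim <- simulate_pair(sim_truth(seed = 71))
  expo <- maf_filter(sim$exposure, 0.01)
  g <- sensitivity_grid(expo, sim$outcome, sim$ld,
                        grid_spec(5e-8, 1e-3))
  expect_equal(nrow(g), 1L)
  ins <- select_instruments(expo, sim$ld, 5e-8, 1e-3)
  direct <- dispatch_mr(harmonize_pair(ins$variants, sim$outcome))
  expect_equal(g$beta, direct$beta)
  expect_equal(g$method, direct$method)
})

test_that("tightening the r2 threshold never adds instruments to a cell", {
  sim <- simulate_pair(sim_truth(seed = 72))
  expo <- maf_filter(sim$exposure, 0.01)
  g <- sensitivity_grid(expo, sim$outcome, sim$ld)
  expect_equal(nrow(g), 16L)
  for (p in unique(g$p_threshold)) {
    cell <- g[g$p_threshold == p, ]
    cell <- cell[order(cell$r2_threshold), ]
    expect_true(all(diff(cell$n_variants) >= 0))
  }
})

test_that("cells without instruments are marked empty, not failed", {
  sim <- simulate_pair(sim_truth(L = 2, seed = 73))
  expo <- maf_filter(sim$exposure, 0.01)
  expo$pval[expo$pval < 5e-6] <- 1e-8  # clears 5e-8 but not 5e-10
  g <- sensitivity_grid(expo, sim$outcome, sim$ld,
                        grid_spec(c(5e-8, 5e-10), 1e-3))
  expect_equal(g$empty, c(FALSE, TRUE))
  expo$pval <- 1
  expect_error(sensitivity_grid(expo, sim$outcome, sim$ld), "no grid cell")
})

test_that("the checklist encodes the six robustness criteria", {
  primary <- mk_res(0.19, 0.05)
  egger <- mk_res(0.18, 0.1, intercept_p = 0.8)
  wmed <- mk_res(0.2, 0.06)
  wmod <- mk_res(0.25, 0.08)
  grid <- data.frame(p_threshold = rep(c(5e-8, 5e-6), each = 2),
                     r2_threshold = rep(c(1e-3, 1e-2), 2),
                     empty = FALSE, beta = 0.2)
  sh <- mk_res(0.15, 0.05)
  st <- list(mr = mk_res(0.19, 0.05), n_removed = 0L)
  rev_null <- mk_res(0.01, 0.04)

  all_ok <- robustness_checklist(primary, egger, wmed, wmod, grid, sh, st,
                                 rev_null)
  expect_equal(all_ok$status, rep("pass", 6))

  # escape clause: significant intercept is tolerated with a significant slope
  egger_sig <- mk_res(0.3, 0.05, intercept_p = 0.01)
  c1 <- robustness_checklist(primary, egger_sig, wmed, wmod, grid, sh, st,
                             rev_null)
  expect_equal(c1$status[1], "pass")
  egger_bad <- mk_res(0.05, 0.1, intercept_p = 0.01)
  c1b <- robustness_checklist(primary, egger_bad, wmed, wmod, grid, sh, st,
                              rev_null)
  expect_equal(c1b$status[1], "fail")

  # a sign-flipped grid cell breaks directional consistency on its margin
  grid_bad <- grid
  grid_bad$beta[grid_bad$p_threshold == 5e-8 &
                  grid_bad$r2_threshold == 1e-2] <- -0.1
  c2 <- robustness_checklist(primary, egger, wmed, wmod, grid_bad, sh, st,
                             rev_null)
  expect_equal(c2$status[2], "fail")
  expect_equal(c2$status[3], "pass")

  # empty cells are excluded, not failures
  grid_empty <- grid
  grid_empty$empty[2] <- TRUE
  grid_empty$beta[2] <- NA
  c3 <- robustness_checklist(primary, egger, wmed, wmod, grid_empty, sh, st,
                             rev_null)
  expect_equal(c3$status[2], "pass")

  # Steiger removals with a sign flip fail; none removed passes regardless
  st_flip <- list(mr = mk_res(-0.02, 0.05), n_removed = 2L)
  c5 <- robustness_checklist(primary, egger, wmed, wmod, grid, sh, st_flip,
                             rev_null)
  expect_equal(c5$status[5], "fail")

  # significant positive reverse association fails criterion 6
  rev_pos <- mk_res(0.3, 0.05)
  c6 <- robustness_checklist(primary, egger, wmed, wmod, grid, sh, st,
                             rev_pos)
  expect_equal(c6$status[6], "fail")

  # missing inputs are reported, never silently true
  miss <- robustness_checklist(primary, egger, wmed, wmod, grid,
                               slopehunter = NULL, steiger = st,
                               reverse = not_evaluable("none"))
  expect_equal(miss$status[4], "not-evaluated")
  expect_equal(miss$status[6], "not-evaluated")
})

test_that("specificity verdicts are plain interval checks", {
  conv <- or_ci_to_beta_se(1.21, 1.08, 1.35)
  primary <- mk_res(unname(conv["beta"]), unname(conv["se"]))
  # comparator with a null effect sits outside the positive primary CI
  verd <- specificity_compare(primary, list(null_condition = mk_res(0, 0.03),
                                            same = mk_res(primary$beta, 0.1)))
  expect_false(verd$within_primary_ci[1])
  expect_true(verd$within_primary_ci[2])

  set.seed(74)
  comps <- lapply(1:50, function(i) mk_res(rnorm(1, 0.1, 0.2),
                                           runif(1, 0.01, 0.2)))
  names(comps) <- sprintf("c%d", 1:50)
  verd2 <- specificity_compare(primary, comps)
  betas <- vapply(comps, `[[`, numeric(1), "beta")
  pvals <- vapply(comps, `[[`, numeric(1), "pval")
  expect_equal(verd2$within_primary_ci,
               unname(betas >= primary$ci_low & betas <= primary$ci_high))
  expect_equal(verd2$nominal_positive, unname(pvals < 0.05 & betas > 0))
})

test_that("reverse MR swaps roles and honors the threshold fallback", {
  sim <- simulate_pair(sim_truth(
    reverse = list(L_rev = 2L, eta_sd = 0.25, theta_rev = 0), seed = 75))
  # swapped twice is the forward analysis
  fwd <- reverse_mr(sim$exposure, sim$outcome, sim$ld)
  ins <- select_instruments(sim$exposure, sim$ld, 5e-8, 1e-3)
  direct <- dispatch_mr(harmonize_pair(ins$variants, sim$outcome))
  expect_equal(fwd$beta, direct$beta)

  # two outcome instruments dispatch to fixed-effects IVW
  rev <- reverse_mr(sim$outcome, sim$exposure, sim$ld)
  expect_equal(rev$method, "ivw_fixed")
  expect_equal(rev$n_variants, 2L)
  expect_equal(attr(rev, "p_threshold_used"), 5e-8)

  # nothing significant at either tier: typed non-result
  weak <- sim$outcome
  weak$pval <- pmax(weak$pval, 1e-3)
  expect_true(is_not_evaluable(reverse_mr(weak, sim$exposure, sim$ld)))
})

test_that("effective sample sizes follow the balanced-design formula", {
  expect_equal(effective_n(500, 500), 1000)
  # arithmetic oracle on the primary outcome cohort's printed counts
  n_case <- 3018; n_control <- 994582
  expect_equal(effective_n(n_case, n_control),
               4 * n_case * n_control / (n_case + n_control))
  ov <- effective_overlap(3018, 994582, 21021, 391160, 0)
  expect_equal(as.numeric(ov), 0)
  expect_equal(attr(ov, "n_eff_1"), effective_n(3018, 994582))
  half <- effective_overlap(500, 500, 2000, 2000, 500)
  expect_equal(as.numeric(half), 0.5)
  expect_error(effective_overlap(500, 500, 2000, 2000, 5000), "exceeds")
  expect_error(effective_n(0, 10), "positive")
})
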