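# Univariable estimators, dispatch, heterogeneity, and Steiger filtering.

test_that("Wald ratio is the outcome/exposure effect ratio", {
  h <- make_h(0.5, 0.02, 0.25, 0.1)
  res <- wald_ratio(h)
  expect_equal(res$beta, 0.5)
  expect_equal(res$se, 0.2)

  h0 <- make_h(0.5, 0.02, 0, 0.1)
  res0 <- wald_ratio(h0)
  expect_equal(res0$beta, 0)
  expect_equal(res0$pval, 1)

  expect_error(wald_ratio(make_h(0, 0.02, 0.1, 0.1)), "beta_exp")
  expect_error(wald_ratio(make_h(c(1, 1), c(1, 1), c(1, 1), c(1, 1))),
               "exactly one")
})

test_that("first-order Wald SE agrees with the full delta method for strong
           instruments", {
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    be <- runif(1, 0.05, 0.3) * sample(c(-1, 1), 1)
    se_e <- abs(be) / runif(1, 10, 40)     # |beta_exp|/se_exp > 10
    theta <- runif(1, -0.4, 0.4)
    se_o <- se_e * runif(1, 1, 3)
    h <- make_h(be, se_e, theta * be, se_o)
    first <- wald_ratio(h)$se
    second <- sqrt(se_o^2 / be^2 + (theta * be)^2 * se_e^2 / be^4)
    worst <- max(worst, abs(first - second) / second)
  }
  expect_lt(worst, 0.1)
})

test_that("IVW reduces correctly under homogeneity and symmetry", {
  # identical ratios, equal weights: estimate = ratio, Q = 0, fixed = random
  h <- make_h(c(0.2, 0.1), c(0.02, 0.02), c(0.1, 0.05), c(0.03, 0.03))
  f <- ivw(h, "fixed")
  m <- ivw(h, "multiplicative_random")
  expect_equal(f$beta, 0.5)
  expect_equal(f$Q, 0)
  expect_equal(m$se, f$se)

  # equal beta_exp and weights, ratios 0 and 1: estimate = 0.5
  h2 <- make_h(c(0.2, 0.2), c(0.02, 0.02), c(0, 0.2), c(0.03, 0.03))
  expect_equal(ivw(h2)$beta, 0.5)

  expect_error(ivw(make_h(1, 1, 1, 1)), "wald_ratio")
})

test_that("IVW matches the weighted-least-squares oracle", {
  set.seed(12)
  for (i in 1:50) {
    L <- sample(4:35, 1)
    h <- make_h(rnorm(L, 0, 0.2), runif(L, 0.01, 0.04),
                rnorm(L, 0, 0.1), runif(L, 0.01, 0.08))
    fit <- lm(beta_out ~ beta_exp - 1, data = h, weights = 1 / h$se_out^2)
    sm <- summary(fit)
    expect_equal(ivw(h, "fixed")$beta, unname(coef(fit)[1]),
                 tolerance = 1e-10)
    expect_equal(ivw(h, "fixed")$se,
                 unname(sm$coefficients[1, 2] / sm$sigma), tolerance = 1e-10)
    expect_equal(ivw(h, "multiplicative_random")$se,
                 unname(sm$coefficients[1, 2] / sm$sigma * max(1, sm$sigma)),
                 tolerance = 1e-10)
  }
})

test_that("Egger slope/intercept behave as a weighted regression", {
  set.seed(13)
  L <- 20
  be <- abs(rnorm(L, 0.2, 0.05))
  se_o <- runif(L, 0.01, 0.05)
  bo <- 0.3 * be + rnorm(L, 0, se_o)
  h <- make_h(be, rep(0.01, L), bo, se_o)
  res <- mr_egger(h)
  fit <- lm(bo ~ be, weights = 1 / se_o^2)
  expect_equal(res$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(res$egger_intercept, unname(coef(fit)[1]), tolerance = 1e-10)

  # translation equivariance: adding c to beta_out moves only the intercept
  h2 <- h
  h2$beta_out <- h$beta_out + 0.05
  res2 <- mr_egger(h2)
  expect_equal(res2$beta, res$beta, tolerance = 1e-12)
  expect_equal(res2$egger_intercept, res$egger_intercept + 0.05,
               tolerance = 1e-12)

  # exact linearity through the origin: intercept 0, slope = IVW
  h3 <- make_h(be, rep(0.01, L), 0.3 * be, se_o)
  res3 <- mr_egger(h3)
  expect_equal(res3$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(res3$beta, ivw(h3)$beta, tolerance = 1e-12)

  expect_error(mr_egger(make_h(1:2, 1:2, 1:2, 1:2)), ">= 3")
})

test_that("weighted median interpolates the weighted quantile function", {
  h <- make_h(c(1, 1, 1), rep(0.01, 3), c(1, 2, 9), rep(1, 3))
  expect_equal(suppressWarnings(weighted_median(h, reps = 50, seed = 1))$beta,
               2)

  set.seed(14)
  for (i in 1:500) {
    L <- sample(3:30, 1)
    theta <- rnorm(L)
    w <- runif(L, 0.1, 5)
    expect_equal(mrforge:::weighted_quantile(theta, w, 0.5),
                 brute_force_weighted_quantile(theta, w, 0.5),
                 tolerance = 1e-12)
  }
  expect_error(weighted_median(h, reps = 1, seed = 1), "reps")
  expect_error(weighted_median(h, reps = 500), "seed")
})

test_that("weighted mode finds the dominant ratio cluster", {
  # degenerate: identical ratios for any bandwidth multiplier
  h <- make_h(c(0.2, 0.4, 0.1), rep(0.01, 3), c(0.1, 0.2, 0.05), rep(1, 3))
  for (phi in c(0.25, 1, 4)) {
    expect_equal(suppressWarnings(
      weighted_mode(h, phi = phi, reps = 50, seed = 1))$beta,
      0.5, tolerance = 1e-2)
  }
  expect_error(weighted_mode(h, phi = 0, reps = 500, seed = 1), "phi")

  # bimodal with 60/40 weight split: mode sits at the heavier cluster
  set.seed(15)
  hits <- 0L
  for (i in 1:20) {
    r1 <- rnorm(12, 0.2, 0.02)
    r2 <- rnorm(8, 1.0, 0.02)
    h2 <- make_h(rep(1, 20), rep(0.01, 20), c(r1, r2), rep(0.03, 20))
    m <- suppressWarnings(weighted_mode(h2, reps = 50, seed = i))$beta
    if (abs(m - 0.2) < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("mode grid argmax is stable under 10x grid refinement", {
  set.seed(16)
  for (i in 1:200) {
    L <- sample(5:30, 1)
    theta <- rnorm(L, 0, 1)
    w <- runif(L, 0.5, 2)
    coarse <- mrforge:::mode_estimate_rows(matrix(theta, 1), matrix(w, 1),
                                           phi = 1, grid_n = 512L)
    fine <- mrforge:::mode_estimate_rows(matrix(theta, 1), matrix(w, 1),
                                         phi = 1, grid_n = 5120L)
    step <- diff(range(theta)) / 511
    expect_lte(abs(coarse - fine), step * 1.5)
  }
})

test_that("dispatch follows the variant-count rule", {
  h <- make_h(runif(5, 0.1, 0.3), rep(0.01, 5), runif(5), rep(0.05, 5))
  expect_equal(dispatch_mr(h[1, ])$method, "wald")
  expect_equal(dispatch_mr(h[1:2, ])$method, "ivw_fixed")
  expect_equal(dispatch_mr(h[1:3, ])$method, "ivw_fixed")
  expect_equal(dispatch_mr(h[1:4, ])$method, "ivw_mre")
  expect_equal(dispatch_mr(h)$method, "ivw_mre")
  expect_error(dispatch_mr(h[0, ]), "empty")
})

test_that("Cochran's Q is zero for collinear data and additive in outliers", {
  be <- c(0.1, 0.2, 0.3)
  h <- make_h(be, rep(0.01, 3), 0.4 * be, rep(0.02, 3))
  q <- cochran_q(h, 0.4)
  expect_equal(q$Q, 0)
  expect_equal(q$Q_pval, 1)

  h$beta_out[3] <- h$beta_out[3] + 0.1
  q2 <- cochran_q(h, 0.4)
  expect_equal(q2$Q, (0.1 / 0.02)^2)

  # moment check: homogeneous data give Q/(L-1) ~ 1 on average
  set.seed(17)
  ratios <- replicate(1000, {
    L <- 10
    be <- runif(L, 0.1, 0.3)
    se <- runif(L, 0.02, 0.05)
    h <- make_h(be, rep(0.01, L), 0.2 * be + rnorm(L, 0, se), se)
    cochran_q(h, ivw(h)$beta)$Q / (L - 1)
  })
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("Steiger filtering removes outcome-first variants", {
  h <- make_h(c(10 * 0.02, 2 * 0.02), rep(0.02, 2),
              c(2 * 0.02, 10 * 0.02), rep(0.02, 2),
              n_exp = 5e4, n_out = 5e4)
  got <- steiger_filter(h)
  expect_equal(got$steiger$table$keep, c(TRUE, FALSE))
  expect_equal(got$steiger$n_removed, 1L)
  expect_equal(nrow(got$harmonized), 1L)

  h$n_exp <- NA
  expect_error(steiger_filter(h), "sample sizes")
})

test_that("estimators are scale-equivariant and respect ratio bounds", {
  set.seed(18)
  L <- 15
  h <- make_h(abs(rnorm(L, 0.2, 0.05)), rep(0.01, L),
              rnorm(L, 0.05, 0.03), runif(L, 0.02, 0.05))
  c_scale <- 2.5
  h2 <- h
  h2$beta_exp <- h$beta_exp * c_scale
  for (f in list(function(x) ivw(x)$beta,
                 function(x) mr_egger(x)$beta,
                 function(x) weighted_median(x, reps = 100, seed = 3)$beta)) {
    expect_equal(f(h2), f(h) / c_scale, tolerance = 1e-6)
  }
  mode1 <- weighted_mode(h, reps = 100, seed = 3)$beta
  mode2 <- weighted_mode(h2, reps = 100, seed = 3)$beta
  expect_equal(mode2, mode1 / c_scale, tolerance = 0.02)

  r <- h$beta_out / h$beta_exp
  wm <- weighted_median(h, reps = 100, seed = 3)$beta
  expect_true(wm >= min(r) && wm <= max(r))
  md <- weighted_mode(h, reps = 100, seed = 3)$beta
  expect_true(md >= min(r) - 0.1 && md <= max(r) + 0.1)

  # a single duplicated variant reproduces the Wald ratio
  hd <- rbind(h[1, ], h[1, ])
  expect_equal(ivw(hd)$beta, wald_ratio(h[1, ])$beta, tolerance = 1e-12)
})
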