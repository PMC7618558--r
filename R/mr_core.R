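# Univariable MR estimators, estimator dispatch, heterogeneity and
# Steiger directionality filtering.
#
# All causal estimates are on the log-odds (or SD) scale of the outcome per
# log-odds increase in the exposure; odds ratios are exponentiated betas.
# p-values are two-sided normal except Cochran's Q (chi-square).

make_mr_result <- function(method, n_variants, beta, se,
                           Q = NA_real_, Q_pval = NA_real_,
                           egger_intercept = NA_real_,
                           egger_intercept_se = NA_real_,
                           egger_intercept_pval = NA_real_,
                           bootstrap_reps = NA_integer_, seed = NA_integer_) {
  z <- z975()
  structure(list(
    method = method, n_variants = as.integer(n_variants),
    beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se,
    or = exp(beta), or_ci_low = exp(beta - z * se),
    or_ci_high = exp(beta + z * se),
    pval = if (se > 0) two_sided_p(beta / se) else as.numeric(beta == 0),
    Q = Q, Q_pval = Q_pval,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_pval = egger_intercept_pval,
    bootstrap_reps = bootstrap_reps, seed = seed
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s, %d variant%s): OR %.3f [95%%CI %.3f-%.3f], P = %.3g\n",
              x$method, x$n_variants, if (x$n_variants == 1L) "" else "s",
              x$or, x$or_ci_low, x$or_ci_high, x$pval))
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  intercept %.4f (SE %.4f), P_intercept = %.3g\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_pval))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Wald ratio estimator for a single-variant instrument
#'
#' `beta = beta_out / beta_exp` with first-order delta-method standard error
#' `se = |se_out / beta_exp|` (the exposure sampling error is second-order
#' for strong instruments).
#'
#' @param h A `harmonized_set` with exactly one variant.
#' @return An `mr_result` with method `"wald"`.
#' @export
wald_ratio <- function(h) {
  if (nrow(h) != 1L) stop("wald_ratio requires exactly one variant")
  if (h$beta_exp == 0) stop("beta_exp is zero; Wald ratio undefined")
  make_mr_result("wald", 1L,
                 beta = h$beta_out / h$beta_exp,
                 se = abs(h$se_out / h$beta_exp))
}

#' Inverse-variance weighted estimator
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin with weights `1/se_out^2`:
#' `theta = sum(w b_exp b_out) / sum(w b_exp^2)`. With
#' `effects = "fixed"` the SE is the WLS formula `1/sqrt(sum(w b_exp^2))`;
#' with `"multiplicative_random"` it is inflated by
#' `max(1, sqrt(Q / (L - 1)))` where Q is Cochran's heterogeneity statistic,
#' so the random-effects SE never shrinks below the fixed-effects SE.
#'
#' @param h A `harmonized_set` with at least two variants.
#' @param effects `"fixed"` or `"multiplicative_random"`.
#' @return An `mr_result`.
#' @export
ivw <- function(h, effects = c("multiplicative_random", "fixed")) {
  effects <- match.arg(effects)
  L <- nrow(h)
  if (L < 2L) stop("ivw requires >= 2 variants; use wald_ratio for one")
  w <- 1 / h$se_out^2
  denom <- sum(w * h$beta_exp^2)
  theta <- sum(w * h$beta_exp * h$beta_out) / denom
  se_fixed <- sqrt(1 / denom)
  Q <- sum(w * (h$beta_out - theta * h$beta_exp)^2)
  Q_pval <- stats::pchisq(Q, df = L - 1, lower.tail = FALSE)
  if (effects == "fixed") {
    make_mr_result("ivw_fixed", L, theta, se_fixed, Q, Q_pval)
  } else {
    se <- se_fixed * max(1, sqrt(Q / (L - 1)))
    make_mr_result("ivw_mre", L, theta, se, Q, Q_pval)
  }
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects *with* intercept
#' (weights `1/se_out^2`), after orienting all variants so `beta_exp >= 0`
#' (Egger is not orientation-invariant; this is the established convention).
#' The slope is the causal estimate; a nonzero intercept indicates
#' directional pleiotropy. Both SEs are inflated by
#' `max(1, sqrt(Q_egger / (L - 2)))` and p-values are two-sided normal.
#'
#' @param h A `harmonized_set` with at least three variants.
#' @return An `mr_result` with method `"egger"` and intercept diagnostics.
#' @export
mr_egger <- function(h) {
  L <- nrow(h)
  if (L < 3L) stop("mr_egger requires >= 3 variants")
  s <- ifelse(h$beta_exp < 0, -1, 1)
  x <- s * h$beta_exp
  y <- s * h$beta_out
  w <- 1 / h$se_out^2
  X <- cbind(intercept = 1, slope = x)
  A <- crossprod(X, w * X)
  coefs <- drop(solve(A, crossprod(X, w * y)))
  resid <- y - drop(X %*% coefs)
  Qe <- sum(w * resid^2)
  scale <- max(1, sqrt(Qe / (L - 2)))
  ses <- sqrt(diag(solve(A))) * scale
  make_mr_result(
    "egger", L, beta = unname(coefs["slope"]), se = unname(ses["slope"]),
    Q = Qe, Q_pval = stats::pchisq(Qe, df = L - 2, lower.tail = FALSE),
    egger_intercept = unname(coefs["intercept"]),
    egger_intercept_se = unname(ses["intercept"]),
    egger_intercept_pval = unname(
      two_sided_p(coefs["intercept"] / ses["intercept"]))
  )
}

ratio_estimates <- function(h) {
  list(theta = h$beta_out / h$beta_exp,
       w = h$beta_exp^2 / h$se_out^2)
}

# Parametric bootstrap over (beta_exp, beta_out); returns a reps-long vector
# of re-estimates produced by `estimate_fun(theta_draws, w_draws)` where the
# arguments are reps x L matrices.
param_bootstrap <- function(h, reps, seed, estimate_fun) {
  set.seed(seed)
  L <- nrow(h)
  be <- matrix(stats::rnorm(reps * L, mean = rep(h$beta_exp, each = reps),
                            sd = rep(h$se_exp, each = reps)), reps, L)
  bo <- matrix(stats::rnorm(reps * L, mean = rep(h$beta_out, each = reps),
                            sd = rep(h$se_out, each = reps)), reps, L)
  theta <- bo / be
  w <- sweep(be^2, 2L, h$se_out^2, "/")
  estimate_fun(theta, w)
}

#' Weighted median estimator
#'
#' Per-variant ratio estimates `beta_out/beta_exp` weighted by
#' `beta_exp^2/se_out^2`; the estimate is the weighted empirical median using
#' the half-weight cumulative convention `S_j = cumsum(w)_j - w_j/2` with
#' linear interpolation. The estimate is consistent when more than half of
#' the total weight comes from valid instruments. The SE is a parametric
#' bootstrap: `(beta_exp, beta_out)` are redrawn from normal distributions
#' centered at the observed effects with the reported SEs.
#'
#' @param h A `harmonized_set` with at least three variants.
#' @param reps Bootstrap replicates (default 5000; fewer than 100 warns,
#'   fewer than 2 is an error).
#' @param seed RNG seed for the bootstrap (mandatory; no silent
#'   nondeterminism).
#' @return An `mr_result` with method `"weighted_median"`.
#' @export
weighted_median <- function(h, reps = 5000L, seed) {
  if (nrow(h) < 3L) stop("weighted_median requires >= 3 variants")
  if (missing(seed)) stop("seed is mandatory for the bootstrap")
  if (reps < 2L) stop("reps must be >= 2")
  if (reps < 100L) warning("reps < 100 gives an unstable bootstrap SE")
  r <- ratio_estimates(h)
  est <- weighted_quantile(r$theta, r$w, 0.5)
  boots <- param_bootstrap(h, reps, seed, function(theta, w) {
    vapply(seq_len(nrow(theta)),
           function(i) weighted_quantile(theta[i, ], w[i, ], 0.5),
           numeric(1L))
  })
  make_mr_result("weighted_median", nrow(h), est, stats::sd(boots),
                 bootstrap_reps = as.integer(reps), seed = as.integer(seed))
}

# Modal estimate(s) from rows of ratio/weight matrices via weighted
# normal-kernel density evaluated on a per-row grid of `grid_n` points.
mode_estimate_rows <- function(theta, w, phi, grid_n = 512L) {
  B <- nrow(theta); L <- ncol(theta)
  wn <- w / rowSums(w)
  mu <- rowSums(wn * theta)
  sdw <- sqrt(rowSums(wn * (theta - mu)^2))
  iqr <- vapply(seq_len(B), function(i) {
    q <- weighted_quantile(theta[i, ], w[i, ], c(0.25, 0.75))
    q[2L] - q[1L]
  }, numeric(1L))
  bw <- phi * 0.9 * pmin(sdw, iqr / 1.349) * L^(-1 / 5)
  bw[bw <= 0 | !is.finite(bw)] <- 1e-8
  lo <- apply(theta, 1L, min) - 3 * bw
  step <- (apply(theta, 1L, max) + 3 * bw - lo) / (grid_n - 1L)
  grid <- lo + outer(rep(1, B), 0:(grid_n - 1L)) * step
  dens <- matrix(0, B, grid_n)
  for (j in seq_len(L)) {
    dens <- dens + wn[, j] * stats::dnorm((grid - theta[, j]) / bw) / bw
  }
  grid[cbind(seq_len(B), max.col(dens, ties.method = "first"))]
}

#' Weighted mode estimator
#'
#' The argmax of a weighted normal-kernel density over the per-variant ratio
#' estimates, evaluated on a dense grid. Bandwidth follows the modified
#' Silverman rule `phi * 0.9 * min(sd, IQR/1.349) * L^(-1/5)` computed on the
#' weighted ratio sample. Consistent when the largest share of instrument
#' weight comes from valid instruments. SE by the same parametric bootstrap
#' as [weighted_median()], summarized by the MAD of the bootstrap modes (the
#' originating implementation's convention; the bootstrap mode distribution
#' has occasional far-off modes that would inflate a plain SD).
#'
#' @param h A `harmonized_set` with at least three variants.
#' @param phi Bandwidth multiplier (> 0), default 1.
#' @param reps Bootstrap replicates.
#' @param seed RNG seed (mandatory).
#' @param grid_n Grid resolution for the density argmax.
#' @return An `mr_result` with method `"weighted_mode"`.
#' @export
weighted_mode <- function(h, phi = 1, reps = 5000L, seed, grid_n = 512L) {
  if (nrow(h) < 3L) stop("weighted_mode requires >= 3 variants")
  if (phi <= 0) stop("phi must be positive")
  if (missing(seed)) stop("seed is mandatory for the bootstrap")
  if (reps < 2L) stop("reps must be >= 2")
  if (reps < 100L) warning("reps < 100 gives an unstable bootstrap SE")
  r <- ratio_estimates(h)
  est <- mode_estimate_rows(matrix(r$theta, 1L), matrix(r$w, 1L), phi, grid_n)
  boots <- param_bootstrap(h, reps, seed, function(theta, w) {
    mode_estimate_rows(theta, w, phi, grid_n)
  })
  make_mr_result("weighted_mode", nrow(h), est, stats::mad(boots),
                 bootstrap_reps = as.integer(reps), seed = as.integer(seed))
}

#' Estimator dispatch rule
#'
#' One variant: Wald ratio. Two or three variants: fixed-effects IVW. More
#' than three: IVW with multiplicative random effects.
#'
#' @param h A non-empty `harmonized_set`.
#' @return An `mr_result`.
#' @export
dispatch_mr <- function(h) {
  L <- nrow(h)
  if (L == 0L) stop("empty harmonized set")
  if (L == 1L) return(wald_ratio(h))
  if (L <= 3L) return(ivw(h, "fixed"))
  ivw(h, "multiplicative_random")
}

#' Cochran's heterogeneity statistic at a given causal effect
#'
#' `Q = sum((beta_out - theta beta_exp)^2 / se_out^2)`, referred to a
#' chi-square distribution with `L - 1` degrees of freedom.
#'
#' @param h A `harmonized_set` with at least two variants.
#' @param theta Causal effect at which residual heterogeneity is evaluated.
#' @return List with `Q` and `Q_pval`.
#' @export
cochran_q <- function(h, theta) {
  L <- nrow(h)
  if (L < 2L) stop("cochran_q requires >= 2 variants")
  Q <- sum((h$beta_out - theta * h$beta_exp)^2 / h$se_out^2)
  list(Q = Q, Q_pval = stats::pchisq(Q, df = L - 1, lower.tail = FALSE))
}

#' Steiger directionality filtering
#'
#' Per variant and per trait, the variance explained is approximated by
#' `r^2 = z^2 / (z^2 + n - 2)` with `z = beta/se` (observed scale, no
#' prevalence input needed). Variants explaining more variance in the outcome
#' than in the exposure are removed as candidate reverse-causal variants.
#'
#' @param h A `harmonized_set` with per-variant sample sizes `n_exp`, `n_out`.
#' @return List with `harmonized` (the filtered set) and `steiger`, a list
#'   holding the per-variant table (`variant_id, r2_exposure, r2_outcome,
#'   keep`) and `n_removed`.
#' @export
steiger_filter <- function(h) {
  if (any(is.na(h$n_exp)) || any(is.na(h$n_out))) {
    stop("per-variant sample sizes n_exp and n_out are required")
  }
  z2e <- (h$beta_exp / h$se_exp)^2
  z2o <- (h$beta_out / h$se_out)^2
  r2e <- z2e / (z2e + h$n_exp - 2)
  r2o <- z2o / (z2o + h$n_out - 2)
  keep <- r2e > r2o
  tab <- data.frame(variant_id = h$variant_id,
                    r2_exposure = r2e, r2_outcome = r2o, keep = keep,
                    stringsAsFactors = FALSE)
  kept <- h[keep, , drop = FALSE]
  attrs <- attributes(h)
  for (a in c("exposure_label", "outcome_label")) attr(kept, a) <- attrs[[a]]
  class(kept) <- class(h)
  list(harmonized = kept,
       steiger = list(table = tab, n_removed = sum(!keep)))
}
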