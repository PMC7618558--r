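# Collider-bias slope correction for GWAS of conditional phenotypes
# (e.g. a progression trait ascertained only in those with an index event).
#
# Model: among incidence-associated variants, paired effects (b_I, b_P) are a
# two-component mixture. Component 1 ("incidence-only", mixing proportion
# pi) has no true progression effect, so the observed progression effect is
# purely collider-induced: b_P = b * b_I + eps, eps ~ N(0, tau^2), with
# b_I ~ N(0, s1^2). Component 2 is a free bivariate normal absorbing
# variants with true progression effects. EM alternates responsibilities and
# (pi, b, tau^2, s1^2, component-2 moments). The fitted slope b is then used
# to de-bias all progression effects: beta_adj = beta_P - b * beta_I with
# se_adj = sqrt(se_P^2 + b^2 se_I^2).

dbvnorm <- function(x, y, mu, sigma) {
  det <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2]^2
  inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[1, 2], sigma[1, 1]),
                2, 2) / det
  dx <- x - mu[1L]; dy <- y - mu[2L]
  q <- inv[1, 1] * dx^2 + 2 * inv[1, 2] * dx * dy + inv[2, 2] * dy^2
  exp(-q / 2) / (2 * pi * sqrt(det))
}

#' Slope-Hunter-style collider-bias adjustment
#'
#' Estimates the collider-induced slope `b` between incidence and
#' (conditional) progression effects via an EM-fitted two-component mixture
#' over incidence-associated variants, then returns progression summary
#' statistics adjusted as `beta_P - b * beta_I` with delta-method SEs.
#' Downstream MR should be rerun on the adjusted effects.
#'
#' @param incidence Variant associations for the index (incidence) trait.
#' @param progression Variant associations for the conditional (progression)
#'   trait; the shared variant set with `incidence` is used.
#' @param p_threshold Incidence significance threshold used to pre-select the
#'   variants the mixture is fitted on; default 5e-8.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param seed RNG seed for the responsibility initializations (mandatory).
#' @param n_restarts Number of EM starts: one robust deterministic start
#'   (responsibilities from residuals around the weighted-median ratio
#'   slope) plus `n_restarts - 1` random starts; the highest-log-likelihood
#'   solution is kept. The mixture likelihood is multimodal because the free
#'   bivariate component can also fit the incidence-only cluster.
#' @return List with `fit` (class `slope_hunter_fit`: `b_hat`,
#'   `cluster_probs`, `pi`, `tau2`, `converged`, `n_iter`, `loglik`) and
#'   `adjusted`, the progression collection with de-biased `beta`/`se`
#'   (p-values recomputed).
#' @export
slope_hunter_adjust <- function(incidence, progression, p_threshold = 5e-8,
                                max_iter = 500L, tol = 1e-6, seed,
                                n_restarts = 5L) {
  if (missing(seed)) stop("seed is mandatory for EM initialization")
  ids <- intersect(incidence$variant_id, progression$variant_id)
  if (length(ids) < 10L) stop("need >= 10 shared variants to fit the mixture")
  inc <- incidence[match(ids, incidence$variant_id), , drop = FALSE]
  pro <- progression[match(ids, progression$variant_id), , drop = FALSE]
  sel <- inc$pval <= p_threshold
  if (sum(sel) < 10L) {
    stop("fewer than 10 incidence-associated variants at P<=",
         format(p_threshold))
  }
  x <- inc$beta[sel]
  y <- pro$beta[sel]
  n <- length(x)

  set.seed(seed)
  # Robust start: slope from the weighted median of per-variant ratios;
  # points close to that line get high component-1 responsibility.
  b0 <- weighted_quantile(y / x, x^2, 0.5)
  res0 <- y - b0 * x
  s0 <- stats::mad(res0)
  if (s0 <= 0) s0 <- stats::sd(res0) + 1e-12
  g_robust <- pmin(pmax(exp(-0.5 * (res0 / (2 * s0))^2), 0.05), 0.95)
  starts <- c(list(g_robust),
              replicate(max(0L, n_restarts - 1L),
                        stats::runif(n, 0.25, 0.75), simplify = FALSE))

  best <- NULL
  for (g0 in starts) {
    fit <- sh_em(x, y, g0, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  b <- best$b
  g <- best$g

  fit <- structure(list(b_hat = b, cluster_probs = g, pi = best$pi,
                        tau2 = best$tau2, converged = best$converged,
                        n_iter = best$n_iter, loglik = best$loglik,
                        variant_id = ids[sel]),
                   class = "slope_hunter_fit")

  adj <- pro
  adj$beta <- pro$beta - b * inc$beta
  adj$se <- sqrt(pro$se^2 + b^2 * inc$se^2)
  adj$pval <- two_sided_p(adj$beta / adj$se)
  rownames(adj) <- NULL
  list(fit = fit, adjusted = adj)
}

sh_em <- function(x, y, g, max_iter, tol) {
  ll_old <- -Inf
  ll <- -Inf
  converged <- FALSE
  iter <- 0L
  pi1 <- 0.5; b <- 0; tau2 <- 1; s1sq <- 1
  for (iter in seq_len(max_iter)) {
    # M step (uses current responsibilities g)
    pi1 <- min(max(mean(g), 1e-3), 1 - 1e-3)
    b <- sum(g * x * y) / sum(g * x^2)
    tau2 <- max(sum(g * (y - b * x)^2) / sum(g), 1e-12)
    s1sq <- max(sum(g * x^2) / sum(g), 1e-12)
    w2 <- 1 - g
    sw2 <- sum(w2)
    mu2 <- c(sum(w2 * x), sum(w2 * y)) / sw2
    dx <- x - mu2[1L]; dy <- y - mu2[2L]
    sig2 <- matrix(c(sum(w2 * dx^2), sum(w2 * dx * dy),
                     sum(w2 * dx * dy), sum(w2 * dy^2)) / sw2, 2, 2)
    sig2 <- sig2 + diag(1e-10, 2)
    # E step
    f1 <- stats::dnorm(x, 0, sqrt(s1sq)) * stats::dnorm(y, b * x, sqrt(tau2))
    f2 <- dbvnorm(x, y, mu2, sig2)
    denom <- pi1 * f1 + (1 - pi1) * f2
    denom[denom < 1e-300] <- 1e-300
    g <- pi1 * f1 / denom
    ll <- sum(log(denom))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(b = b, g = g, pi = pi1, tau2 = tau2, converged = converged,
       n_iter = iter, loglik = ll)
}

#' @export
print.slope_hunter_fit <- function(x, ...) {
  cat(sprintf(
    "Slope-Hunter fit: b = %.4f (pi = %.2f, tau2 = %.2e, %s in %d iter)\n",
    x$b_hat, x$pi, x$tau2,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
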