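# Multivariable IVW MR: direct effect of an exposure adjusting for a second.

#' Joint instrument union for multivariable MR
#'
#' Takes the union of variants reaching the significance threshold in either
#' exposure and clumps them jointly, ranking by the minimum of the two
#' per-variant p-values.
#'
#' @param exp1,exp2 Variant-association data.frames for the two exposures.
#' @param ld An `ld_matrix` or `NULL`.
#' @param p_threshold Significance threshold applied to either exposure.
#' @param r2_threshold LD r-squared clumping threshold.
#' @param window_bp Clumping window; default 10 Mb.
#' @return Character vector of retained variant ids, in acceptance order.
#' @export
mv_instrument_union <- function(exp1, exp2, ld, p_threshold = 5e-8,
                                r2_threshold = 1e-3, window_bp = 1e7) {
  if (nrow(exp1) == 0L || nrow(exp2) == 0L) {
    stop("both exposure collections must be non-empty")
  }
  sig1 <- exp1$variant_id[exp1$pval <= p_threshold]
  sig2 <- exp2$variant_id[exp2$pval <= p_threshold]
  ids <- union(sig1, sig2)
  if (length(ids) == 0L) {
    stop("no variant reaches P<=", format(p_threshold), " in either exposure")
  }
  i1 <- match(ids, exp1$variant_id)
  i2 <- match(ids, exp2$variant_id)
  p1 <- ifelse(is.na(i1), Inf, exp1$pval[i1])
  p2 <- ifelse(is.na(i2), Inf, exp2$pval[i2])
  src <- ifelse(!is.na(i1), "exp1", "exp2")
  pick <- function(col) {
    ifelse(src == "exp1", exp1[[col]][i1], exp2[[col]][i2])
  }
  combined <- data.frame(variant_id = ids,
                         chrom = pick("chrom"),
                         pos = pick("pos"),
                         pval = pmin(p1, p2),
                         stringsAsFactors = FALSE)
  ld_clump(combined, ld, r2_threshold, window_bp)$variant_id
}

#' Assemble a multivariable harmonized set
#'
#' Harmonizes each exposure against the outcome (so all effects refer to the
#' same per-variant effect allele) and intersects the results.
#'
#' @param exp1,exp2,outcome Variant-association data.frames.
#' @param variant_ids Optional restriction to these variants (e.g. from
#'   [mv_instrument_union()]).
#' @param palindrome_eaf_limit Passed to [harmonize_pair()].
#' @return A data.frame (class `mv_harmonized_set`) with columns
#'   `variant_id, beta_exp1, se_exp1, beta_exp2, se_exp2, beta_out, se_out`.
#' @export
harmonize_mv <- function(exp1, exp2, outcome, variant_ids = NULL,
                         palindrome_eaf_limit = 0.42) {
  if (!is.null(variant_ids)) {
    exp1 <- exp1[exp1$variant_id %in% variant_ids, , drop = FALSE]
    exp2 <- exp2[exp2$variant_id %in% variant_ids, , drop = FALSE]
    outcome <- outcome[outcome$variant_id %in% variant_ids, , drop = FALSE]
  }
  h1 <- harmonize_pair(exp1, outcome, palindrome_eaf_limit)
  h2 <- harmonize_pair(exp2, outcome, palindrome_eaf_limit)
  ids <- intersect(h1$variant_id, h2$variant_id)
  if (length(ids) == 0L) stop("no variants shared across all three traits")
  a <- h1[match(ids, h1$variant_id), , drop = FALSE]
  b <- h2[match(ids, h2$variant_id), , drop = FALSE]
  out <- data.frame(variant_id = ids,
                    beta_exp1 = a$beta_exp, se_exp1 = a$se_exp,
                    beta_exp2 = b$beta_exp, se_exp2 = b$se_exp,
                    beta_out = a$beta_out, se_out = a$se_out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("mv_harmonized_set", "data.frame"))
}

#' Multivariable inverse-variance weighted MR
#'
#' Weighted least squares of the outcome effects on both exposures' effects
#' with no intercept and weights `1/se_out^2`; each coefficient is that
#' exposure's direct effect conditional on the other. SEs are inflated by
#' `max(1, residual scale)` as in univariable multiplicative random effects.
#' A conditional instrument-strength diagnostic is reported per exposure as
#' the mean squared standardized residual of that exposure's effects after
#' weighted regression on the other exposure (a regression-of-exposures
#' heuristic, not the Sanderson-Windmeijer statistic).
#'
#' @param m An `mv_harmonized_set` (or data.frame with the same columns),
#'   with at least 3 variants (exposures + 1).
#' @return An `mvmr_result`: data.frame `estimates` (per-exposure beta, se,
#'   CI, p), `n_variants`, `conditional_F`.
#' @export
mvmr_ivw <- function(m) {
  L <- nrow(m)
  k <- 2L
  if (L < k + 1L) stop("mvmr_ivw requires at least ", k + 1L, " variants")
  w <- 1 / m$se_out^2
  X <- cbind(exp1 = m$beta_exp1, exp2 = m$beta_exp2)
  zero_col <- apply(X == 0, 2L, all)
  if (any(zero_col)) {
    # an exposure with no genetic effects carries no information: drop it,
    # so the other exposure's estimate collapses to univariable IVW
    warning("exposure '", colnames(X)[zero_col][1L],
            "' has all-zero effects; reporting univariable IVW for the other")
    keep <- which(!zero_col)[1L]
    uni <- ivw(data.frame(beta_exp = X[, keep], se_exp = 0.01,
                          beta_out = m$beta_out, se_out = m$se_out),
               "multiplicative_random")
    z <- z975()
    est <- data.frame(exposure = colnames(X),
                      beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, pval = NA_real_,
                      stringsAsFactors = FALSE)
    est[keep, 2:6] <- c(uni$beta, uni$se, uni$ci_low, uni$ci_high, uni$pval)
    return(structure(list(estimates = est, n_variants = L,
                          conditional_F = stats::setNames(
                            rep(NA_real_, 2L), colnames(X)),
                          condition_number = Inf),
                     class = "mvmr_result"))
  }
  Xw <- sqrt(w) * X
  cond <- kappa(Xw, exact = TRUE)
  if (!is.finite(cond) || cond > 1e8) {
    stop("rank-deficient design (collinear exposures); condition number ",
         format(cond, digits = 4))
  }
  A <- crossprod(X, w * X)
  coefs <- drop(solve(A, crossprod(X, w * m$beta_out)))
  resid <- m$beta_out - drop(X %*% coefs)
  sigma <- sqrt(sum(w * resid^2) / (L - k))
  ses <- sqrt(diag(solve(A))) * max(1, sigma)
  z <- z975()
  est <- data.frame(exposure = colnames(X), beta = coefs, se = ses,
                    ci_low = coefs - z * ses, ci_high = coefs + z * ses,
                    pval = two_sided_p(coefs / ses),
                    row.names = NULL, stringsAsFactors = FALSE)
  cf <- c(conditional_f(m$beta_exp1, m$se_exp1, m$beta_exp2),
          conditional_f(m$beta_exp2, m$se_exp2, m$beta_exp1))
  structure(list(estimates = est, n_variants = L,
                 conditional_F = stats::setNames(cf, colnames(X)),
                 condition_number = cond),
            class = "mvmr_result")
}

conditional_f <- function(beta_j, se_j, beta_other) {
  fit <- stats::lm(beta_j ~ beta_other, weights = 1 / se_j^2)
  mean((stats::resid(fit) / se_j)^2)
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable IVW MR (%d variants):\n", x$n_variants))
  for (i in seq_len(nrow(x$estimates))) {
    e <- x$estimates[i, ]
    cat(sprintf("  %s: OR %.3f [95%%CI %.3f-%.3f], P = %.3g (cond. F %.1f)\n",
                e$exposure, exp(e$beta), exp(e$ci_low), exp(e$ci_high),
                e$pval, x$conditional_F[[e$exposure]]))
  }
  invisible(x)
}
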