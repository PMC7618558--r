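# Approximate-Bayes-factor colocalization between two traits over a region.
#
# Five hypotheses: H0 no causal variant for either trait; H1 causal variant
# for trait 1 only; H2 trait 2 only; H3 distinct causal variants; H4 one
# shared causal variant. All hypothesis arithmetic is in log space with
# log-sum-exp so regions with |z| well above 40 do not overflow.

#' Wakefield approximate log Bayes factor
#'
#' For one variant with effect `beta`, standard error `se` and prior effect
#' variance `W`, with `z = beta/se` and shrinkage `r = W/(W + se^2)`:
#' `log ABF = 0.5 (log(1 - r) + r z^2)` — the log ratio of the marginal
#' likelihood under effect ~ N(0, W) to the point-null likelihood.
#'
#' @param beta,se Effect and standard error (vectorized; `se > 0`).
#' @param W Prior variance of the true effect (> 0).
#' @return Log approximate Bayes factor(s) favoring association.
#' @export
wakefield_log_abf <- function(beta, se, W) {
  stopifnot(all(se > 0), W > 0)
  r <- W / (W + se^2)
  z <- beta / se
  0.5 * (log(1 - r) + r * z^2)
}

#' Construct a regional two-trait association pair
#'
#' @param data data.frame with columns `variant_id, beta_t1, se_t1, beta_t2,
#'   se_t2`.
#' @param trait_types Character(2), each `"quantitative"` or `"case_control"`
#'   (recorded for provenance; both use the same default prior scale).
#' @param p1,p2 Per-variant prior probability of association with trait 1 /
#'   trait 2 alone; defaults 1e-4.
#' @param p12 Per-variant prior probability of association with both traits;
#'   default 1e-5.
#' @param sd_prior Prior effect SDs `sqrt(W)` for the two traits; default
#'   0.2 each (log-odds scale for case-control traits).
#' @return An object of class `regional_pair`.
#' @export
regional_pair <- function(data,
                          trait_types = c("quantitative", "case_control"),
                          p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                          sd_prior = c(0.2, 0.2)) {
  need <- c("variant_id", "beta_t1", "se_t1", "beta_t2", "se_t2")
  if (!all(need %in% names(data))) {
    stop("regional data needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(data) < 1L) stop("at least one variant is required")
  if (!(p1 > 0 && p2 > 0 && p12 > 0 && p1 + p2 + p12 < 1)) {
    stop("priors must satisfy p1, p2, p12 > 0 and p1 + p2 + p12 < 1")
  }
  if (any(data$se_t1 <= 0) || any(data$se_t2 <= 0)) stop("all se must be > 0")
  structure(list(data = data, trait_types = trait_types,
                 p1 = p1, p2 = p2, p12 = p12, sd_prior = sd_prior),
            class = "regional_pair")
}

#' Five-hypothesis colocalization posteriors
#'
#' Computes per-variant Wakefield log ABFs for each trait, combines them into
#' the five hypothesis sums (H1 proportional to `p1 * sum(BF1)`, H2 to
#' `p2 * sum(BF2)`, H3 to `p1 p2 (sum(BF1) sum(BF2) - sum(BF1*BF2))`, H4 to
#' `p12 * sum(BF1*BF2)`, H0 to 1), normalizes, and evaluates the conditional
#' colocalization probability `PP4 / (PP3 + PP4)`.
#'
#' @param r A [regional_pair()].
#' @return An object of class `coloc_result`: `pp` (named numeric, H0..H4
#'   summing to 1), `conditional_h4` (numeric, or `NA` when `PP3 + PP4` is
#'   zero — see [conditional_h4()]), `n_variants`.
#' @export
coloc_posteriors <- function(r) {
  d <- r$data
  l1 <- wakefield_log_abf(d$beta_t1, d$se_t1, r$sd_prior[1L]^2)
  l2 <- wakefield_log_abf(d$beta_t2, d$se_t2, r$sd_prior[2L]^2)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lh <- c(h0 = 0,
          h1 = log(r$p1) + ls1,
          h2 = log(r$p2) + ls2,
          h3 = log(r$p1) + log(r$p2) + logdiffexp(ls1 + ls2, ls12),
          h4 = log(r$p12) + ls12)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  ch4 <- conditional_h4(pp)
  structure(list(pp = pp,
                 conditional_h4 = if (is_not_evaluable(ch4)) NA_real_ else ch4,
                 n_variants = nrow(d)),
            class = "coloc_result")
}

#' Conditional colocalization probability
#'
#' `PP4 / (PP3 + PP4)`: the probability of a shared causal variant
#' conditional on there being at least one causal variant for each trait.
#'
#' @param pp Normalized five-hypothesis posterior vector (H0..H4 order).
#' @return Numeric in \[0, 1\], or a typed [not_evaluable()] when
#'   `PP3 + PP4 = 0`.
#' @export
conditional_h4 <- function(pp) {
  if (inherits(pp, "coloc_result")) pp <- pp$pp
  stopifnot(length(pp) == 5L)
  denom <- pp[4L] + pp[5L]
  if (denom == 0) {
    return(not_evaluable("PP3 + PP4 = 0: no support for either trait-pair hypothesis"))
  }
  unname(pp[5L] / denom)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "Colocalization (%d variants): PP0 %.3f PP1 %.3f PP2 %.3f PP3 %.3f PP4 %.3f\n",
    x$n_variants, x$pp[1L], x$pp[2L], x$pp[3L], x$pp[4L], x$pp[5L]))
  cat(sprintf("  conditional P(shared | both causal) = %.3f\n",
              x$conditional_h4))
  invisible(x)
}

#' @export
as.data.frame.coloc_result <- function(x, ...) {
  data.frame(pp_h0 = x$pp[1L], pp_h1 = x$pp[2L], pp_h2 = x$pp[3L],
             pp_h3 = x$pp[4L], pp_h4 = x$pp[5L],
             conditional_h4 = x$conditional_h4,
             n_variants = x$n_variants, row.names = NULL)
}
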