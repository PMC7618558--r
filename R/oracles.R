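# Independent reference implementations used only for validation. These are
# deliberately written as brute-force or closed-form alternatives to the
# production code paths and are never called by them.

#' Brute-force weighted quantile (validation oracle)
#'
#' Evaluates the weighted empirical quantile function by an explicit scan of
#' the sorted sample using the half-weight cumulative convention, with
#' manual linear interpolation. Independent of [weighted_median()]'s
#' implementation path; used to validate it.
#'
#' @param x Sample values.
#' @param w Non-negative weights.
#' @param q Quantile level in (0, 1).
#' @return The interpolated weighted quantile.
#' @export
brute_force_weighted_quantile <- function(x, w, q = 0.5) {
  o <- order(x)
  xs <- x[o]
  ws <- w[o] / sum(w)
  n <- length(xs)
  s <- numeric(n)
  acc <- 0
  for (j in seq_len(n)) {
    s[j] <- acc + ws[j] / 2
    acc <- acc + ws[j]
  }
  if (q <= s[1L]) return(xs[1L])
  if (q >= s[n]) return(xs[n])
  j <- max(which(s < q))
  xs[j] + (xs[j + 1L] - xs[j]) * (q - s[j]) / (s[j + 1L] - s[j])
}

#' Exhaustive colocalization posteriors by causal-configuration enumeration
#' (validation oracle)
#'
#' Enumerates every causal-variant assignment for the two traits (none, or
#' one of the J variants each) and accumulates un-normalized hypothesis
#' masses directly, without the sum-product shortcuts or log-space tricks of
#' [coloc_posteriors()]. Feasible for small regions only.
#'
#' @param r A [regional_pair()] with at most ~15 variants.
#' @return Named numeric vector of the five normalized posteriors (h0..h4).
#' @export
enumerate_coloc_posteriors <- function(r) {
  d <- r$data
  J <- nrow(d)
  bf1 <- exp(wakefield_log_abf(d$beta_t1, d$se_t1, r$sd_prior[1L]^2))
  bf2 <- exp(wakefield_log_abf(d$beta_t2, d$se_t2, r$sd_prior[2L]^2))
  m <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (j in seq_len(J)) {
    m["h1"] <- m["h1"] + r$p1 * bf1[j]
    m["h2"] <- m["h2"] + r$p2 * bf2[j]
    m["h4"] <- m["h4"] + r$p12 * bf1[j] * bf2[j]
    for (k in seq_len(J)) {
      if (k != j) m["h3"] <- m["h3"] + r$p1 * r$p2 * bf1[j] * bf2[k]
    }
  }
  m / sum(m)
}

#' Pairwise verification of a greedy LD-clumping result (validation oracle)
#'
#' Checks the two defining properties of the clumped set without rerunning
#' the greedy algorithm: (a) no two retained variants on the same chromosome
#' within the window have r-squared at or above the threshold; (b) every
#' discarded variant is within the window of a retained variant of better
#' rank (p-value, then chromosome, position, id) with r-squared at or above
#' the threshold.
#'
#' @param records Input variant-association data.frame.
#' @param ld `ld_matrix` or `NULL`.
#' @param r2_threshold,window_bp Clumping parameters.
#' @param kept The clumped result to verify.
#' @return `TRUE` if both properties hold, otherwise `FALSE`.
#' @export
verify_clump <- function(records, ld, r2_threshold, window_bp, kept) {
  ids <- records$variant_id
  r2 <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(r2) <- 1
  if (!is.null(ld)) {
    inb <- intersect(ids, ld$variant_ids)
    if (length(inb) > 1L) r2[inb, inb] <- ld$r[inb, inb]^2
  }
  rank_key <- order(records$pval, records$chrom, records$pos,
                    records$variant_id)
  rank <- match(seq_len(nrow(records)), rank_key)
  in_kept <- records$variant_id %in% kept$variant_id
  near <- function(i, j) {
    records$chrom[i] == records$chrom[j] &&
      abs(records$pos[i] - records$pos[j]) <= window_bp
  }
  for (i in which(in_kept)) {
    for (j in which(in_kept)) {
      if (i < j && near(i, j) &&
          r2[ids[i], ids[j]] >= r2_threshold) return(FALSE)
    }
  }
  for (i in which(!in_kept)) {
    dominated <- FALSE
    for (j in which(in_kept)) {
      if (rank[j] < rank[i] && near(i, j) &&
          r2[ids[i], ids[j]] >= r2_threshold) { dominated <- TRUE; break }
    }
    if (!dominated) return(FALSE)
  }
  TRUE
}
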