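# Internal numeric helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (b numerically equal to or above a).
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Weighted empirical quantile with the half-weight cumulative convention
# S_j = cumsum(w)_j - w_j/2 (weights normalized), linearly interpolated.
weighted_quantile <- function(x, w, probs = 0.5) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  vapply(probs, function(q) {
    if (q <= s[1L]) return(x[1L])
    n <- length(x)
    if (q >= s[n]) return(x[n])
    stats::approx(s, x, xout = q, ties = "ordered")$y
  }, numeric(1L))
}

z975 <- function() stats::qnorm(0.975)

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

# Reverse complement of an allele string (A/C/G/T alphabet).
revcomp <- function(a) {
  vapply(a, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

#' Typed non-result for analyses that cannot be evaluated
#'
#' Several operations (cis instrument construction, reverse MR, the
#' conditional colocalization probability) can end without a numeric answer
#' for structural reasons rather than errors. They return this typed object
#' so callers can distinguish "not evaluable" from failure.
#'
#' @param reason Character description of why the quantity is not evaluable.
#' @return An object of class `not_evaluable`.
#' @export
not_evaluable <- function(reason) {
  structure(list(reason = reason), class = "not_evaluable")
}

#' @rdname not_evaluable
#' @param x Object to test.
#' @export
is_not_evaluable <- function(x) inherits(x, "not_evaluable")

#' @export
print.not_evaluable <- function(x, ...) {
  cat("<not evaluable>", x$reason, "\n")
  invisible(x)
}
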