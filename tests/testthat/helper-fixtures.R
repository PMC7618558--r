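# In-code fixtures shared across test files.

# Minimal variant-association data.frame with canonical columns.
make_assoc <- function(variant_id, beta, se,
                       chrom = "1", pos = seq_along(variant_id) * 1e6,
                       ea = "A", oa = "G", eaf = 0.3, n = 1e5,
                       pval = 2 * pnorm(-abs(beta / se))) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = pval,
             n = n, n_case = NA, n_control = NA,
             stringsAsFactors = FALSE)
}

# Harmonized-set data.frame straight from effect vectors (bypasses
# harmonization; estimator tests only need the numeric columns).
make_h <- function(beta_exp, se_exp, beta_out, se_out,
                   n_exp = 1e5, n_out = 1e5) {
  L <- length(beta_exp)
  data.frame(variant_id = sprintf("v%d", seq_len(L)),
             beta_exp = beta_exp, se_exp = se_exp,
             beta_out = beta_out, se_out = se_out,
             pval_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
             pval_out = 2 * pnorm(-abs(beta_out / se_out)),
             eaf = 0.3, n_exp = n_exp, n_out = n_out,
             stringsAsFactors = FALSE)
}

# Random correlation matrix via a low-rank factor structure.
random_ld <- function(ids, seed) {
  set.seed(seed)
  n <- length(ids)
  A <- matrix(rnorm(n * 3L), n, 3L)
  S <- tcrossprod(A) + diag(runif(n, 0.5, 2))
  D <- diag(1 / sqrt(diag(S)))
  ld_matrix(ids, D %*% S %*% D)
}

# Random variant panel on a handful of chromosomes for clumping tests.
random_panel <- function(n, seed) {
  set.seed(seed)
  make_assoc(sprintf("s%03d", seq_len(n)),
             beta = rnorm(n, 0, 0.1), se = runif(n, 0.01, 0.05),
             chrom = as.character(sample(1:3, n, replace = TRUE)),
             pos = sample(1:5e6, n))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
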