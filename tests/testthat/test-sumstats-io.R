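# Reading, validation, OR conversion, harmonization, and result round-trips.

test_that("read_sumstats parses well-formed files and enforces invariants", {
  df <- make_assoc(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                   se = c(0.02, 0.03, 0.01))
  path <- write_tsv(df, tempfile(fileext = ".tsv"))
  got <- read_sumstats(path)
  expect_equal(nrow(got), 3L)
  expect_equal(got$beta, df$beta)
  expect_equal(attr(got, "n_dropped"), 0L)

  bad <- df
  bad$se[2L] <- 0
  path2 <- write_tsv(bad, tempfile(fileext = ".tsv"))
  expect_message(got2 <- read_sumstats(path2), "1 row")
  expect_equal(got2$variant_id, c("rs1", "rs3"))
  expect_equal(attr(got2, "n_dropped"), 1L)

  allbad <- df
  allbad$pval <- 0
  path3 <- write_tsv(allbad, tempfile(fileext = ".tsv"))
  expect_error(suppressMessages(read_sumstats(path3)), "no valid rows")
})

test_that("header aliases via column_map give the same records", {
  df <- make_assoc(c("rs1", "rs2"), beta = c(0.1, -0.2), se = c(0.02, 0.03))
  alias <- df
  names(alias)[names(alias) == "effect_allele"] <- "EA"
  names(alias)[names(alias) == "pval"] <- "P"
  p1 <- write_tsv(df, tempfile(fileext = ".tsv"))
  p2 <- write_tsv(alias, tempfile(fileext = ".tsv"))
  got1 <- read_sumstats(p1)
  got2 <- read_sumstats(p2, column_map = c(EA = "effect_allele", P = "pval"))
  attr(got1, "n_dropped") <- attr(got2, "n_dropped") <- NULL
  expect_equal(got1, got2)
  expect_error(read_sumstats(p2), "effect_allele")
})

test_that("rows violating the case/control-total identity are dropped", {
  df <- make_assoc(c("rs1", "rs2"), beta = c(0.1, 0.2), se = c(0.02, 0.02))
  df$n <- 100; df$n_case <- c(40, 30); df$n_control <- c(60, 60)
  path <- write_tsv(df, tempfile(fileext = ".tsv"))
  expect_message(got <- read_sumstats(path))
  expect_equal(got$variant_id, "rs1")
})

test_that("odds-ratio/CI conversion inverts the Wald construction", {
  z <- qnorm(0.975)
  got <- or_ci_to_beta_se(exp(1), exp(1 - z * 0.5), exp(1 + z * 0.5))
  expect_equal(unname(got["beta"]), 1, tolerance = 1e-12)
  expect_equal(unname(got["se"]), 0.5, tolerance = 1e-12)

  # independent quantile oracle: invert pnorm numerically
  z_or <- uniroot(function(q) pnorm(q) - 0.975, c(1, 3), tol = 1e-14)$root
  got2 <- or_ci_to_beta_se(1.21, 1.08, 1.35)
  expect_equal(unname(got2["beta"]), log(1.21), tolerance = 1e-12)
  expect_equal(unname(got2["se"]), (log(1.35) - log(1.08)) / (2 * z_or),
               tolerance = 1e-10)

  expect_error(or_ci_to_beta_se(1, 1, 1), "degenerate")
  expect_error(or_ci_to_beta_se(-1, 0.5, 2), "positive")
})

test_that("harmonization aligns alleles, flips, and drops ambiguity", {
  ex <- make_assoc(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, 0.3),
                   se = rep(0.02, 3))
  ou <- ex
  ou$beta <- c(0.05, -0.08, 0.02)
  # rs2: alleles swapped in the outcome file
  ou$effect_allele[2L] <- "G"; ou$other_allele[2L] <- "A"
  ou$eaf[2L] <- 0.7
  h <- harmonize_pair(ex, ou)
  expect_equal(nrow(h), 3L)
  expect_equal(h$beta_out, c(0.05, 0.08, 0.02))
  expect_equal(h$flipped_flag, c(FALSE, TRUE, FALSE))

  # reverse-complement match (exposure A/G vs outcome T/C) is not a flip
  ou2 <- ex
  ou2$effect_allele <- "T"; ou2$other_allele <- "C"
  h2 <- harmonize_pair(ex, ou2)
  expect_equal(h2$beta_out, ou2$beta)
  expect_false(any(h2$flipped_flag))

  # incompatible allele sets are dropped and counted
  ou3 <- ex
  ou3$effect_allele[1L] <- "C"
  h3 <- harmonize_pair(ex, ou3)
  expect_equal(nrow(h3), 2L)
  expect_equal(attr(h3, "n_dropped_incompatible"), 1L)
})

test_that("palindromic variants follow the frequency-resolution rule", {
  pal <- function(eaf_exp, eaf_out, limit = 0.42) {
    ex <- make_assoc("rs1", 0.1, 0.02, ea = "A", oa = "T", eaf = eaf_exp)
    ou <- make_assoc("rs1", 0.05, 0.02, ea = "A", oa = "T", eaf = eaf_out)
    tryCatch(harmonize_pair(ex, ou, palindrome_eaf_limit = limit),
             error = function(e) NULL)
  }
  expect_null(pal(0.5, 0.5))        # unresolvable at any limit
  expect_null(pal(0.45, 0.45))      # inside the ambiguous band
  h <- pal(0.2, 0.25)               # clear minor allele, same orientation
  expect_equal(nrow(h), 1L)
  expect_true(h$palindromic_flag)
  expect_null(pal(0.2, 0.8))        # orientations disagree -> dropped
})

test_that("harmonization is idempotent and conserves variant counts", {
  set.seed(4)
  n <- 30
  ex <- make_assoc(sprintf("rs%d", 1:n), beta = rnorm(n, 0, 0.1),
                   se = runif(n, 0.01, 0.05), eaf = runif(n, 0.05, 0.95))
  ou <- ex
  ou$beta <- rnorm(n, 0, 0.1)
  # shuffle some outcome alleles, plant palindromes and incompatibles
  swap <- 1:10
  ou$effect_allele[swap] <- "G"; ou$other_allele[swap] <- "A"
  ou$beta[swap] <- -ou$beta[swap]; ou$eaf[swap] <- 1 - ou$eaf[swap]
  ex$effect_allele[11:14] <- "A"; ex$other_allele[11:14] <- "T"
  ou$effect_allele[11:14] <- "A"; ou$other_allele[11:14] <- "T"
  ex$eaf[11:12] <- 0.5
  ou$effect_allele[15] <- "C"
  h <- harmonize_pair(ex, ou)
  n_pal <- attr(h, "n_dropped_palindromic")
  n_inc <- attr(h, "n_dropped_incompatible")
  expect_equal(nrow(h) + n_pal + n_inc, n)

  pair <- mrforge:::harmonized_to_pair(h)
  h2 <- harmonize_pair(pair$exposure, pair$outcome)
  expect_equal(h2$beta_out, h$beta_out)
  expect_equal(h2$beta_exp, h$beta_exp)
  expect_false(any(h2$flipped_flag))
})

test_that("flipping outcome alleles and betas leaves the result unchanged", {
  set.seed(5)
  n <- 12
  ex <- make_assoc(sprintf("rs%d", 1:n), beta = rnorm(n, 0, 0.1),
                   se = runif(n, 0.01, 0.05), eaf = runif(n, 0.1, 0.9))
  ou <- ex
  ou$beta <- rnorm(n, 0, 0.1)
  h1 <- harmonize_pair(ex, ou)
  flip <- ou
  flip$effect_allele <- ou$other_allele
  flip$other_allele <- ou$effect_allele
  flip$beta <- -ou$beta
  flip$eaf <- 1 - ou$eaf
  h2 <- harmonize_pair(ex, flip)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$se_out, h1$se_out)
})

test_that("results round-trip through TSV and JSON at full precision", {
  set.seed(6)
  res <- lapply(1:100, function(i) {
    mrforge:::make_mr_result(sample(c("ivw_mre", "egger"), 1),
                             sample(2:50, 1), rnorm(1), runif(1, 1e-4, 1))
  })
  path <- tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- read.delim(path)
  betas <- vapply(res, `[[`, numeric(1), "beta")
  ses <- vapply(res, `[[`, numeric(1), "se")
  expect_equal(back$beta, betas, tolerance = 1e-12)
  expect_equal(back$se, ses, tolerance = 1e-12)
  expect_equal(back$or, exp(betas), tolerance = 1e-12)

  cl <- coloc_posteriors(simulate_region(TRUE, 20, 0.8, 6, seed = 1))
  jpath <- tempfile(fileext = ".json")
  write_results(cl, jpath, "json")
  back2 <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(unname(unlist(back2$pp)), unname(cl$pp), tolerance = 1e-12)
  expect_equal(back2$conditional_h4, cl$conditional_h4, tolerance = 1e-12)

  expect_error(write_results(res, file.path(tempdir(), "no/dir/x.tsv")))
})
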