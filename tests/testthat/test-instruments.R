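# MAF filtering, greedy LD clumping, instrument strength, cis instruments.

test_that("MAF filter is symmetric in the effect allele", {
  df <- make_assoc(c("a", "b", "c"), beta = rep(0.1, 3), se = rep(0.02, 3),
                   eaf = c(0.005, 0.995, 0.3))
  expect_equal(maf_filter(df, 0.01)$variant_id, "c")
  expect_equal(maf_filter(df, 0), df)
})

test_that("clumping keeps the stronger of two linked variants", {
  df <- make_assoc(c("a", "b"), beta = c(0.3, 0.2), se = c(0.02, 0.02),
                   pos = c(1e6, 1e6 + 1e3), pval = c(1e-40, 1e-20))
  ld <- ld_matrix(c("a", "b"), matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2))
  got <- ld_clump(df, ld, 0.001)
  expect_equal(got$variant_id, "a")

  # same r recorded but different chromosomes: both retained
  df2 <- df
  df2$chrom <- c("1", "2")
  expect_equal(nrow(ld_clump(df2, ld, 0.001)), 2L)

  expect_error(ld_clump(df, ld, 0), "r2_threshold")
  expect_error(ld_clump(df, ld, 1.5), "r2_threshold")
})

test_that("variants absent from the LD panel are assumed uncorrelated", {
  df <- make_assoc(c("a", "b"), beta = c(0.3, 0.2), se = c(0.02, 0.02),
                   pos = c(1e6, 1e6 + 1e3))
  ld <- ld_matrix("a", matrix(1))
  expect_warning(got <- ld_clump(df, ld, 0.001), "absent")
  expect_equal(nrow(got), 2L)
})

test_that("greedy clumping matches the pairwise-constraint oracle on random
           panels and is invariant to row order", {
  for (s in 1:200) {
    n <- sample(10:60, 1L)
    panel <- random_panel(n, seed = 1000 + s)
    ld <- random_ld(panel$variant_id, seed = 2000 + s)
    r2 <- runif(1, 0.005, 0.5)
    win <- sample(c(1e5, 1e6, 5e6), 1L)
    kept <- ld_clump(panel, ld, r2, win)
    expect_true(verify_clump(panel, ld, r2, win, kept))
    shuffled <- panel[sample(nrow(panel)), , drop = FALSE]
    kept2 <- ld_clump(shuffled, ld, r2, win)
    expect_equal(sort(kept2$variant_id), sort(kept$variant_id))
  }
})

test_that("AR(1)-block data clump to the brute-force answer", {
  sim <- simulate_pair(sim_truth(L = 5, n_null_variants = 50, seed = 31))
  sig <- sim$exposure
  kept <- ld_clump(sig, sim$ld, 0.001, 1e7)
  expect_true(verify_clump(sig, sim$ld, 0.001, 1e7, kept))
})

test_that("loosening selection thresholds never shrinks the instrument set", {
  panel <- random_panel(50, seed = 77)
  ld <- random_ld(panel$variant_id, seed = 78)
  counts_p <- sapply(c(1e-6, 1e-4, 1e-2, 1), function(p) {
    nrow(tryCatch(select_instruments(panel, ld, p, 0.01, 1e6)$variants,
                  error = function(e) panel[0, ]))
  })
  expect_true(all(diff(counts_p) >= 0))
  counts_r2 <- sapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(r2) {
    nrow(select_instruments(panel, ld, 1, r2, 1e6)$variants)
  })
  expect_true(all(diff(counts_r2) >= 0))
})

test_that("instrument strength is the squared Wald z", {
  df <- make_assoc("a", beta = 0.1, se = 0.02, pval = 1e-9)
  ins <- select_instruments(df, NULL, 5e-8, 0.001)
  expect_equal(ins$per_variant_F, 25)
  expect_equal(ins$mean_F, 25)

  panel <- random_panel(100, seed = 5)
  ins2 <- select_instruments(panel, NULL, 1, 1)
  expect_equal(ins2$mean_F,
               mean((ins2$variants$beta / ins2$variants$se)^2),
               tolerance = 1e-12)

  expect_error(select_instruments(panel, NULL, 1e-300, 0.001),
               "more lenient")
})

test_that("cis instruments fall back through significance tiers", {
  spec <- cis_spec("GENE", chrom = "5", gene_start = 1e6, gene_end = 1.2e6)
  base <- make_assoc(c("v1", "v2", "out"), beta = c(0.2, 0.1, 0.5),
                     se = rep(0.02, 3), chrom = "5",
                     pos = c(1.05e6, 9e5, 5e6))
  strong <- base; strong$pval <- c(3e-9, 0.5, 1e-30)
  got <- cis_instruments(strong, NULL, spec)
  expect_equal(got$tier_used, 5e-8)
  expect_equal(got$variants$variant_id, "v1")  # 5e6 is outside the window

  mid <- base; mid$pval <- c(2e-7, 0.5, 1e-30)
  expect_equal(cis_instruments(mid, NULL, spec)$tier_used, 5e-6)

  weak <- base; weak$pval <- c(0.01, 0.5, 1e-30)
  expect_true(is_not_evaluable(cis_instruments(weak, NULL, spec)))

  # intragenic restriction excludes the flank variant
  spec_in <- cis_spec("GENE", "5", 1e6, 1.2e6, intragenic_only = TRUE)
  flank <- base; flank$pos[1L] <- 9.5e5; flank$pval <- c(3e-9, 0.5, 1e-30)
  expect_true(is_not_evaluable(cis_instruments(flank, NULL, spec_in)))
})

test_that("loci merge only on identical instrument variant sets", {
  mk <- function(ids) {
    df <- make_assoc(ids, beta = rep(0.2, length(ids)),
                     se = rep(0.02, length(ids)))
    mrforge:::new_instrument_set(df, 5e-8, 0.001, 1e7)
  }
  got <- group_loci(list(F2R = mk("rs1"), F2RL1 = mk("rs1"),
                         PROC = mk("rs2"),
                         VWF = mk(c("rs3", "rs4")),
                         CPB2 = mk(c("rs3", "rs5"))))
  expect_setequal(names(got), c("F2R/F2RL1", "PROC", "VWF", "CPB2"))
})

test_that("LD matrices load from square and long formats", {
  ids <- c("a", "b", "c")
  r <- matrix(c(1, 0.5, 0, 0.5, 1, -0.2, 0, -0.2, 1), 3)
  mpath <- tempfile()
  write.table(r, mpath, row.names = FALSE, col.names = FALSE)
  vpath <- tempfile()
  writeLines(ids, vpath)
  sq <- read_ld_matrix(mpath, vpath)
  expect_equal(sq$r[ids, ids], `dimnames<-`(r, list(ids, ids)))

  lpath <- tempfile(fileext = ".tsv")
  long <- data.frame(id1 = c("a", "b"), id2 = c("b", "c"), r = c(0.5, -0.2))
  write_tsv(long, lpath)
  lg <- read_ld_matrix(lpath)
  expect_equal(lg$r["a", "b"], 0.5)
  expect_equal(lg$r["b", "c"], -0.2)
  expect_equal(lg$r["a", "c"], 0)

  expect_error(ld_matrix(ids, r[, 1:2]))
  expect_error(ld_matrix(c("a", "b"), matrix(c(1, 0.5, 0.4, 1), 2)),
               "symmetric")
})
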