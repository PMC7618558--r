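# Genetic instrument selection: MAF filtering, greedy LD clumping,
# instrument-strength statistics and gene-specific cis instruments.

#' Construct an LD correlation matrix object
#'
#' @param variant_ids Character vector of variant identifiers (order matches
#'   the matrix).
#' @param r Square matrix of signed LD correlations in \[-1, 1\], symmetric
#'   with unit diagonal.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(variant_ids, r) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (length(variant_ids) != nrow(r)) {
    stop("variant_ids length must match LD matrix dimension")
  }
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  if (max(abs(r)) > 1 + 1e-8) stop("LD correlations must lie in [-1, 1]")
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r = r),
            class = "ld_matrix")
}

#' Read an LD matrix from disk
#'
#' Supports the two interchange layouts used for reference-panel LD:
#' a square whitespace-delimited numeric matrix with a sidecar variant list
#' (one id per line), or a long-format TSV with columns `id1, id2, r`.
#'
#' @param path Path to the matrix (square layout) or long-format TSV.
#' @param variants_path Path to the sidecar variant list; `NULL` selects the
#'   long format.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, variants_path = NULL) {
  if (!is.null(variants_path)) {
    ids <- readLines(variants_path)
    ids <- ids[nzchar(ids)]
    r <- as.matrix(utils::read.table(path, header = FALSE))
    return(ld_matrix(ids, r))
  }
  long <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("id1", "id2", "r") %in% names(long))) {
    stop("long-format LD file needs columns id1, id2, r")
  }
  ids <- unique(c(long$id1, long$id2))
  r <- diag(length(ids))
  dimnames(r) <- list(ids, ids)
  for (k in seq_len(nrow(long))) {
    r[long$id1[k], long$id2[k]] <- long$r[k]
    r[long$id2[k], long$id1[k]] <- long$r[k]
  }
  ld_matrix(ids, r)
}

# Pairwise r^2 lookup; variants absent from the panel are treated as
# uncorrelated (r^2 = 0) with a one-time warning.
ld_r2_lookup <- function(ids, ld) {
  n <- length(ids)
  r2 <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(r2) <- 1
  if (is.null(ld)) return(r2)
  present <- ids %in% ld$variant_ids
  if (any(!present)) {
    warning(sum(!present),
            " variant(s) absent from the LD matrix; assuming r^2 = 0")
  }
  inb <- ids[present]
  if (length(inb) > 1L) r2[inb, inb] <- ld$r[inb, inb]^2
  r2
}

#' Filter variants by minor allele frequency
#'
#' Retains records with `min(eaf, 1 - eaf) >= maf_min`.
#'
#' @param records Variant-association data.frame.
#' @param maf_min Minimum minor allele frequency (e.g. 0.01).
#' @return Filtered data.frame (possibly empty).
#' @export
maf_filter <- function(records, maf_min) {
  if (any(is.na(records$eaf))) stop("eaf must be present for all records")
  keep <- pmin(records$eaf, 1 - records$eaf) >= maf_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of summary statistics
#'
#' PLINK-style greedy index selection: variants are ranked by ascending
#' p-value (ties broken by chromosome, position, then variant id, for
#' determinism); the best remaining variant is accepted and every unaccepted
#' variant on the same chromosome within `window_bp` whose squared
#' correlation with it is at least `r2_threshold` is discarded. Output rows
#' preserve acceptance order.
#'
#' @param records Variant-association data.frame.
#' @param ld An `ld_matrix` (or `NULL` for no LD information: all variants
#'   treated as uncorrelated).
#' @param r2_threshold Squared-correlation threshold in (0, 1].
#' @param window_bp Window in base pairs within which LD is considered.
#' @return The retained (index) variants, in acceptance order.
#' @export
ld_clump <- function(records, ld, r2_threshold, window_bp = 1e7) {
  if (!(r2_threshold > 0 && r2_threshold <= 1)) {
    stop("r2_threshold must lie in (0, 1]")
  }
  n <- nrow(records)
  if (n == 0L) return(records)
  ord <- order(records$pval, records$chrom, records$pos, records$variant_id)
  r2 <- ld_r2_lookup(records$variant_id, ld)
  status <- rep.int(0L, n)  # 0 pending, 1 accepted, -1 discarded
  accepted <- integer(0)
  for (i in ord) {
    if (status[i] != 0L) next
    status[i] <- 1L
    accepted <- c(accepted, i)
    near <- which(status == 0L &
                    records$chrom == records$chrom[i] &
                    abs(records$pos - records$pos[i]) <= window_bp)
    if (length(near)) {
      hit <- near[r2[i, near] >= r2_threshold]
      status[hit] <- -1L
    }
  }
  out <- records[accepted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_instrument_set <- function(variants, p_threshold, r2_threshold,
                               clump_window_bp, tier_used = NA_real_) {
  f <- (variants$beta / variants$se)^2
  structure(list(variants = variants,
                 p_threshold = p_threshold,
                 r2_threshold = r2_threshold,
                 clump_window_bp = clump_window_bp,
                 per_variant_F = f,
                 mean_F = mean(f),
                 tier_used = tier_used),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d variant(s), P<=%g, r2<%g, mean F = %.1f\n",
              nrow(x$variants), x$p_threshold, x$r2_threshold, x$mean_F))
  invisible(x)
}

#' Select genetic instruments by significance and LD clumping
#'
#' Applies the significance threshold, clumps the survivors with
#' [ld_clump()], and computes the per-variant F statistic `(beta/se)^2`
#' (the squared Wald z, the standard single-variant instrument-strength
#' approximation) and its arithmetic mean.
#'
#' @param exposure Exposure variant-association data.frame.
#' @param ld An `ld_matrix` or `NULL`.
#' @param p_threshold Significance threshold (e.g. 5e-8).
#' @param r2_threshold LD r-squared threshold (e.g. 0.001).
#' @param window_bp Clumping window; default 10 Mb.
#' @return An `instrument_set`.
#' @export
select_instruments <- function(exposure, ld, p_threshold = 5e-8,
                               r2_threshold = 1e-3, window_bp = 1e7) {
  if (nrow(exposure) == 0L) stop("exposure collection is empty")
  sig <- exposure[exposure$pval <= p_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    stop("no variants reach P<=", format(p_threshold),
         "; consider a more lenient significance tier")
  }
  clumped <- ld_clump(sig, ld, r2_threshold, window_bp)
  new_instrument_set(clumped, p_threshold, r2_threshold, window_bp)
}

#' Specification of a gene-specific cis window
#'
#' @param gene_label Gene (or locus) name.
#' @param chrom Chromosome.
#' @param gene_start,gene_end Gene body coordinates (1-based, inclusive).
#' @param flank_bp Flank added on both sides; default 200 kb.
#' @param intragenic_only If `TRUE`, restrict to the gene body only.
#' @param tier_thresholds Significance tiers tried in order, most stringent
#'   first; defaults 5e-8, 5e-6, 5e-4.
#' @return An object of class `cis_spec`.
#' @export
cis_spec <- function(gene_label, chrom, gene_start, gene_end,
                     flank_bp = 200000L, intragenic_only = FALSE,
                     tier_thresholds = c(5e-8, 5e-6, 5e-4)) {
  stopifnot(gene_start <= gene_end, all(diff(tier_thresholds) > 0))
  structure(list(gene_label = gene_label, chrom = as.character(chrom),
                 gene_start = gene_start, gene_end = gene_end,
                 flank_bp = flank_bp, intragenic_only = intragenic_only,
                 tier_thresholds = tier_thresholds),
            class = "cis_spec")
}

#' Build a gene-specific cis instrument with tiered significance fallback
#'
#' Restricts the exposure associations to the cis window (gene body plus
#' flank, or gene body alone when `intragenic_only`), then tries each
#' significance tier in order; the first tier yielding at least one clumped
#' variant defines the instrument and is recorded in `tier_used`. If no
#' variant passes even the most lenient tier the gene has no valid cis
#' instrument and a typed [not_evaluable()] outcome is returned.
#'
#' @param exposure Exposure variant-association data.frame.
#' @param ld An `ld_matrix` or `NULL`.
#' @param spec A [cis_spec()].
#' @param r2_threshold LD r-squared threshold for clumping.
#' @return An `instrument_set` (with `tier_used` set) or a `not_evaluable`.
#' @export
cis_instruments <- function(exposure, ld, spec, r2_threshold = 1e-3) {
  lo <- if (spec$intragenic_only) spec$gene_start else spec$gene_start - spec$flank_bp
  hi <- if (spec$intragenic_only) spec$gene_end else spec$gene_end + spec$flank_bp
  win <- exposure[exposure$chrom == spec$chrom &
                    !is.na(exposure$pos) &
                    exposure$pos >= lo & exposure$pos <= hi, , drop = FALSE]
  for (tier in spec$tier_thresholds) {
    sig <- win[win$pval <= tier, , drop = FALSE]
    if (nrow(sig) == 0L) next
    clumped <- ld_clump(sig, ld, r2_threshold, window_bp = hi - lo + 1)
    if (nrow(clumped) >= 1L) {
      out <- new_instrument_set(clumped, tier, r2_threshold,
                                hi - lo + 1, tier_used = tier)
      out$gene_label <- spec$gene_label
      return(out)
    }
  }
  not_evaluable(paste0("no-valid-cis-instrument: ", spec$gene_label,
                       " has no cis variant at the most lenient tier"))
}

#' Group gene-specific instruments into loci
#'
#' Genes whose instruments consist of exactly the same variant set are merged
#' under a single locus labeled by the joined gene names; partially
#' overlapping instruments are kept separate.
#'
#' @param gene_instruments Named list of `instrument_set` objects (names are
#'   gene labels). `not_evaluable` entries are skipped.
#' @return Named list of `instrument_set` objects, one per locus.
#' @export
group_loci <- function(gene_instruments) {
  gene_instruments <- Filter(Negate(is_not_evaluable), gene_instruments)
  if (length(gene_instruments) == 0L) return(list())
  keys <- vapply(gene_instruments, function(s) {
    paste(sort(s$variants$variant_id), collapse = "|")
  }, character(1L))
  out <- list()
  for (key in unique(keys)) {
    members <- names(gene_instruments)[keys == key]
    locus <- gene_instruments[[members[1L]]]
    locus$gene_label <- paste(members, collapse = "/")
    out[[locus$gene_label]] <- locus
  }
  out
}
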