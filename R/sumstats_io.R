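# Reading, validation and harmonization of GWAS summary statistics.
#
# The canonical per-variant record ("variant association") is a data.frame
# with columns:
#   variant_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#   pval, n, n_case, n_control
# beta is the per-allele effect of the effect allele: log-odds units for
# binary traits, SD units for quantitative traits. se > 0, pval in (0, 1],
# eaf in [0, 1].

canonical_columns <- function() {
  c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pval", "n", "n_case", "n_control")
}

mandatory_columns <- function() {
  c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a header-rowed, tab-delimited summary-statistics file into the
#' canonical per-variant record layout. Rows violating the record invariants
#' (non-positive standard error, p-value outside (0, 1], allele frequency
#' outside \[0, 1\], identical effect and other alleles, non-ACGT alleles, or
#' `n_case + n_control != n` where all three are present) are dropped with a
#' message reporting the count; only an empty result is an error.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Optional named character vector mapping file headers to
#'   canonical field names, e.g. `c(EA = "effect_allele", P = "pval")`.
#' @return A data.frame of validated variant associations with attribute
#'   `n_dropped` (number of invalid rows removed).
#' @export
read_sumstats <- function(path, column_map = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (h in names(column_map)) {
      idx <- which(names(df) == h)
      if (length(idx)) names(df)[idx[1L]] <- column_map[[h]]
    }
  }
  missing <- setdiff(mandatory_columns(), names(df))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  for (col in setdiff(canonical_columns(), names(df))) df[[col]] <- NA
  df <- df[canonical_columns()]
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_case", "n_control")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  valid <- validate_variant_rows(df)
  n_dropped <- sum(!valid)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped for invariant violations in ",
            basename(path))
  }
  df <- df[valid, , drop = FALSE]
  if (nrow(df) == 0L) stop("no valid rows in ", path)
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

validate_variant_rows <- function(df) {
  allele_ok <- grepl("^[ACGT]+$", df$effect_allele) &
    grepl("^[ACGT]+$", df$other_allele) &
    df$effect_allele != df$other_allele
  se_ok <- is.finite(df$se) & df$se > 0
  p_ok <- is.finite(df$pval) & df$pval > 0 & df$pval <= 1
  beta_ok <- is.finite(df$beta)
  eaf_ok <- is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)
  cc <- !is.na(df$n_case) & !is.na(df$n_control) & !is.na(df$n)
  n_ok <- !cc | (df$n_case + df$n_control == df$n)
  allele_ok & se_ok & p_ok & beta_ok & eaf_ok & n_ok
}

#' Convert an odds ratio with confidence interval to log-odds beta and SE
#'
#' Standard Wald construction: `beta = log(OR)` and
#' `se = (log(ci_high) - log(ci_low)) / (2 z)` with `z` the standard-normal
#' quantile at `(1 + level)/2`.
#'
#' @param or_point Odds ratio point estimate (> 0).
#' @param ci_low,ci_high Confidence limits with `ci_low < or_point < ci_high`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named numeric vector `c(beta =, se =)`.
#' @export
or_ci_to_beta_se <- function(or_point, ci_low, ci_high, level = 0.95) {
  if (any(c(or_point, ci_low, ci_high) <= 0)) {
    stop("odds ratio and confidence limits must be positive")
  }
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  if (!(ci_low < or_point && or_point < ci_high)) {
    stop("degenerate interval: require ci_low < or_point < ci_high")
  }
  z <- stats::qnorm((1 + level) / 2)
  c(beta = log(or_point), se = (log(ci_high) - log(ci_low)) / (2 * z))
}

is_palindromic_pair <- function(ea, oa) ea == revcomp(oa)

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Intersects the two collections on `variant_id` and aligns each outcome
#' effect to the exposure's effect allele. Outcome records whose effect
#' allele equals the exposure's other allele (directly or via reverse
#' complement) have their beta negated and allele frequency complemented.
#' Palindromic variants (effect allele is the reverse complement of the other
#' allele, e.g. A/T or C/G) are retained only when the allele frequency is
#' outside the ambiguous band `[limit, 1 - limit]` on both traits and the
#' minor allele points the same way on both; otherwise they are dropped and
#' counted. Variants with incompatible allele sets are dropped and counted.
#'
#' @param exposure,outcome Variant-association data.frames (see
#'   [read_sumstats()]).
#' @param palindrome_eaf_limit Frequencies in
#'   `(palindrome_eaf_limit, 1 - palindrome_eaf_limit)` are deemed
#'   strand-unresolvable for palindromic variants. Default 0.42.
#' @param exposure_label,outcome_label Trait labels carried on the result.
#' @return A harmonized data.frame (class `harmonized_set`) with columns
#'   `variant_id, chrom, pos, effect_allele, other_allele, eaf, beta_exp,
#'   se_exp, pval_exp, beta_out, se_out, pval_out, n_exp, n_out,
#'   palindromic_flag, flipped_flag`, plus attributes `exposure_label`,
#'   `outcome_label`, `n_dropped_palindromic`, `n_dropped_incompatible`.
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_eaf_limit = 0.42,
                           exposure_label = "exposure",
                           outcome_label = "outcome") {
  if (nrow(exposure) == 0L || nrow(outcome) == 0L) {
    stop("both exposure and outcome collections must be non-empty")
  }
  for (nm in c("exposure", "outcome")) {
    df <- get(nm)
    if (anyDuplicated(df$variant_id)) {
      warning("duplicate variant_id in ", nm, "; keeping first occurrence")
      assign(nm, df[!duplicated(df$variant_id), , drop = FALSE])
    }
  }
  ids <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(ids) == 0L) stop("empty variant intersection between traits")
  ex <- exposure[match(ids, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(ids, outcome$variant_id), , drop = FALSE]

  pal <- is_palindromic_pair(ex$effect_allele, ex$other_allele)
  keep <- logical(length(ids))
  flip <- logical(length(ids))
  drop_pal <- 0L
  drop_inc <- 0L
  lo <- palindrome_eaf_limit
  hi <- 1 - palindrome_eaf_limit

  for (i in seq_along(ids)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    oea <- ou$effect_allele[i]; ooa <- ou$other_allele[i]
    if (pal[i]) {
      # Allele labels cannot resolve strand for palindromes; use frequencies.
      same_set <- setequal(c(oea, ooa), c(ea, oa))
      if (!same_set) { drop_inc <- drop_inc + 1L; next }
      f_exp <- ex$eaf[i]
      f_out <- if (oea == ea) ou$eaf[i] else 1 - ou$eaf[i]
      resolvable <- !is.na(f_exp) && !is.na(f_out) &&
        (f_exp <= lo || f_exp >= hi) && (f_out <= lo || f_out >= hi)
      agree <- resolvable && sign(f_exp - 0.5) == sign(f_out - 0.5)
      if (!agree) { drop_pal <- drop_pal + 1L; next }
      keep[i] <- TRUE
      flip[i] <- oea != ea
    } else {
      if (oea == ea && ooa == oa) {
        keep[i] <- TRUE
      } else if (oea == oa && ooa == ea) {
        keep[i] <- TRUE; flip[i] <- TRUE
      } else if (revcomp(oea) == ea && revcomp(ooa) == oa) {
        keep[i] <- TRUE
      } else if (revcomp(oea) == oa && revcomp(ooa) == ea) {
        keep[i] <- TRUE; flip[i] <- TRUE
      } else {
        drop_inc <- drop_inc + 1L
      }
    }
  }

  h <- data.frame(
    variant_id = ids,
    chrom = ex$chrom,
    pos = ex$pos,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    eaf = ex$eaf,
    beta_exp = ex$beta,
    se_exp = ex$se,
    pval_exp = ex$pval,
    beta_out = ifelse(flip, -ou$beta, ou$beta),
    se_out = ou$se,
    pval_out = ou$pval,
    n_exp = ex$n,
    n_out = ou$n,
    palindromic_flag = pal,
    flipped_flag = flip,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(h) <- NULL
  if (nrow(h) == 0L) stop("no variants survived harmonization")
  structure(h,
            class = c("harmonized_set", "data.frame"),
            exposure_label = exposure_label,
            outcome_label = outcome_label,
            n_dropped_palindromic = drop_pal,
            n_dropped_incompatible = drop_inc)
}

# Rebuild the two variant-association collections implied by a harmonized
# set (both now on the exposure's effect allele). Used for idempotence
# checks and for reverse MR role swapping.
harmonized_to_pair <- function(h) {
  base <- data.frame(
    variant_id = h$variant_id, chrom = h$chrom, pos = h$pos,
    effect_allele = h$effect_allele, other_allele = h$other_allele,
    eaf = h$eaf, stringsAsFactors = FALSE
  )
  exposure <- cbind(base, data.frame(beta = h$beta_exp, se = h$se_exp,
                                     pval = h$pval_exp, n = h$n_exp,
                                     n_case = NA, n_control = NA))
  outcome <- cbind(base, data.frame(beta = h$beta_out, se = h$se_out,
                                    pval = h$pval_out, n = h$n_out,
                                    n_case = NA, n_control = NA))
  list(exposure = exposure, outcome = outcome)
}

#' Write analysis results to disk
#'
#' Serializes result objects (`mr_result`, `coloc_result`, plain data.frames,
#' or lists of such) to TSV or JSON. Floats are written at full double
#' precision so a round-trip read reproduces them.
#'
#' @param results Result object.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(results_to_list(results), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  } else {
    df <- results_to_df(results)
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("could not write results to ", path)
  }
  invisible(NULL)
}

results_to_df <- function(results) {
  if (is.data.frame(results)) return(as.data.frame(results))
  if (inherits(results, "mr_result")) return(as.data.frame(results))
  if (inherits(results, "coloc_result")) return(as.data.frame(results))
  if (is.list(results) && length(results) &&
      all(vapply(results, inherits, logical(1L), "mr_result"))) {
    return(do.call(rbind, lapply(results, as.data.frame)))
  }
  as.data.frame(results)
}

results_to_list <- function(results) {
  if (inherits(results, "mr_result") || inherits(results, "coloc_result")) {
    return(unclass(results))
  }
  results
}
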