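# Orchestration of the sensitivity grid, robustness checklist, specificity
# comparison, reverse MR, and sample-overlap diagnostics.

#' Sensitivity-grid specification
#'
#' @param p_thresholds Instrument significance thresholds; default
#'   5e-4, 5e-6, 5e-8, 5e-10.
#' @param r2_thresholds LD r-squared thresholds; default 1e-4, 1e-3, 1e-2,
#'   1e-1.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(p_thresholds = c(5e-4, 5e-6, 5e-8, 5e-10),
                      r2_thresholds = c(1e-4, 1e-3, 1e-2, 1e-1)) {
  if (!length(p_thresholds) || !length(r2_thresholds)) {
    stop("thresholds must be non-empty")
  }
  strictly_ordered <- function(x) {
    length(x) == 1L || all(diff(x) > 0) || all(diff(x) < 0)
  }
  if (!strictly_ordered(p_thresholds)) {
    stop("p_thresholds must be strictly ordered")
  }
  if (!strictly_ordered(r2_thresholds)) {
    stop("r2_thresholds must be strictly ordered")
  }
  structure(list(p_thresholds = p_thresholds,
                 r2_thresholds = r2_thresholds), class = "grid_spec")
}

#' MR across a grid of instrument-selection parameters
#'
#' For every `(p_threshold, r2_threshold)` cell: select instruments,
#' harmonize against the outcome, and run the dispatch-rule estimator.
#' Cells yielding no instruments are marked empty, not failed; only an
#' all-empty grid is an error.
#'
#' @param exposure,outcome Variant-association data.frames.
#' @param ld An `ld_matrix` or `NULL`.
#' @param grid A [grid_spec()].
#' @param window_bp Clumping window.
#' @param palindrome_eaf_limit Passed to [harmonize_pair()].
#' @return data.frame with one row per cell: `p_threshold, r2_threshold,
#'   empty, n_variants, method, beta, se, ci_low, ci_high, pval`.
#' @export
sensitivity_grid <- function(exposure, outcome, ld, grid = grid_spec(),
                             window_bp = 1e7, palindrome_eaf_limit = 0.42) {
  cells <- expand.grid(p_threshold = grid$p_thresholds,
                       r2_threshold = grid$r2_thresholds,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    p <- cells$p_threshold[k]
    r2 <- cells$r2_threshold[k]
    res <- tryCatch({
      ins <- select_instruments(exposure, ld, p, r2, window_bp)
      h <- harmonize_pair(ins$variants, outcome, palindrome_eaf_limit)
      dispatch_mr(h)
    }, error = function(e) NULL)
    if (is.null(res)) {
      data.frame(p_threshold = p, r2_threshold = r2, empty = TRUE,
                 n_variants = 0L, method = NA_character_, beta = NA_real_,
                 se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 pval = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(p_threshold = p, r2_threshold = r2, empty = FALSE,
                 n_variants = res$n_variants, method = res$method,
                 beta = res$beta, se = res$se, ci_low = res$ci_low,
                 ci_high = res$ci_high, pval = res$pval,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (all(out$empty)) stop("no grid cell yielded any instrument")
  out
}

sign_consistent <- function(beta, ref_beta) {
  !is.na(beta) & sign(beta) == sign(ref_beta)
}

#' Six-criterion robustness checklist
#'
#' Evaluates the study's robustness criteria for one exposure-outcome pair:
#' 1. MR-Egger suggests no horizontal pleiotropy (intercept p >= alpha, or
#'    intercept p < alpha with causal p < alpha) and all three
#'    pleiotropy-robust estimators (Egger, weighted median, weighted mode)
#'    share the primary estimate's direction.
#' 2. Directional consistency across the LD r-squared grid (cells at the
#'    primary significance threshold).
#' 3. Directional consistency across the significance-threshold grid (cells
#'    at the primary r-squared threshold).
#' 4. The collider-corrected (Slope-Hunter) estimate is directionally
#'    consistent.
#' 5. The Steiger-filtered estimate is directionally consistent, or Steiger
#'    filtering removed no variants.
#' 6. No significant positive reverse association (outcome as exposure).
#'
#' Missing inputs yield status `"not-evaluated"` for the affected criterion,
#' never a silent pass. Empty grid cells are excluded from (2)-(3).
#'
#' @param primary Primary `mr_result`.
#' @param egger,wmedian,wmode Sensitivity `mr_result`s (or `NULL`).
#' @param grid [sensitivity_grid()] output (or `NULL`).
#' @param slopehunter `mr_result` on collider-adjusted effects (or `NULL`).
#' @param steiger List `mr` (post-filter `mr_result`) and `n_removed` (or
#'   `NULL`).
#' @param reverse Reverse-direction `mr_result`, a [not_evaluable()], or
#'   `NULL`.
#' @param alpha Significance level; default 0.05.
#' @param primary_p,primary_r2 The primary analysis's selection parameters,
#'   fixing which grid margin each of criteria 2-3 scans.
#' @return data.frame `criterion` (1-6), `name`, `status`
#'   (`"pass"/"fail"/"not-evaluated"`), `passed` (logical, `NA` when not
#'   evaluated).
#' @export
robustness_checklist <- function(primary, egger = NULL, wmedian = NULL,
                                 wmode = NULL, grid = NULL,
                                 slopehunter = NULL, steiger = NULL,
                                 reverse = NULL, alpha = 0.05,
                                 primary_p = 5e-8, primary_r2 = 1e-3) {
  stopifnot(inherits(primary, "mr_result"))
  ref <- primary$beta

  c1 <- if (is.null(egger) || is.null(wmedian) || is.null(wmode)) NA else {
    no_pleio <- egger$egger_intercept_pval >= alpha ||
      (egger$egger_intercept_pval < alpha && egger$pval < alpha)
    no_pleio && all(sign_consistent(c(egger$beta, wmedian$beta, wmode$beta),
                                    ref))
  }

  grid_margin <- function(fix_col, fix_val) {
    cells <- grid[grid[[fix_col]] == fix_val & !grid$empty, , drop = FALSE]
    if (nrow(cells) == 0L) return(NA)
    all(sign_consistent(cells$beta, ref))
  }
  c2 <- if (is.null(grid)) NA else grid_margin("p_threshold", primary_p)
  c3 <- if (is.null(grid)) NA else grid_margin("r2_threshold", primary_r2)

  c4 <- if (is.null(slopehunter)) NA else sign_consistent(slopehunter$beta, ref)

  c5 <- if (is.null(steiger)) NA else {
    steiger$n_removed == 0L || sign_consistent(steiger$mr$beta, ref)
  }

  c6 <- if (is.null(reverse)) NA
  else if (is_not_evaluable(reverse)) NA
  else !(reverse$pval < alpha && reverse$beta > 0)

  passed <- c(c1, c2, c3, c4, c5, c6)
  data.frame(
    criterion = 1:6,
    name = c("no_pleiotropy_and_robust_estimators_consistent",
             "consistent_across_r2_grid",
             "consistent_across_p_grid",
             "slopehunter_consistent",
             "steiger_consistent_or_no_removal",
             "no_positive_reverse_association"),
    status = ifelse(is.na(passed), "not-evaluated",
                    ifelse(passed, "pass", "fail")),
    passed = passed,
    stringsAsFactors = FALSE
  )
}

#' Compare comparator associations against the primary estimate
#'
#' For each comparator, reports whether its point estimate lies within the
#' primary association's 95% CI and whether it is nominally significant
#' (p < 0.05) with positive sign.
#'
#' @param primary Primary `mr_result` with finite CI.
#' @param comparators Named list of `mr_result`s.
#' @return data.frame `label, beta, within_primary_ci, nominal_positive`.
#' @export
specificity_compare <- function(primary, comparators) {
  stopifnot(is.finite(primary$ci_low), is.finite(primary$ci_high))
  do.call(rbind, lapply(names(comparators), function(lab) {
    cmp <- comparators[[lab]]
    data.frame(label = lab, beta = cmp$beta,
               within_primary_ci = cmp$beta >= primary$ci_low &
                 cmp$beta <= primary$ci_high,
               nominal_positive = cmp$pval < 0.05 & cmp$beta > 0,
               stringsAsFactors = FALSE)
  }))
}

#' Reverse-direction MR
#'
#' Runs the forward machinery with the roles swapped: instruments are
#' selected from the (former) outcome GWAS, tried at each threshold in
#' `p_thresholds` in order, then harmonized against the former exposure and
#' passed through the dispatch rule.
#'
#' @param outcome_as_exposure,exposure_as_outcome Variant-association
#'   data.frames with roles already swapped.
#' @param ld An `ld_matrix` or `NULL`.
#' @param p_thresholds Thresholds tried in order; default 5e-8 then 5e-6.
#' @param r2_threshold,window_bp,palindrome_eaf_limit Selection and
#'   harmonization parameters.
#' @return An `mr_result` (with attribute `p_threshold_used`), or a
#'   [not_evaluable()] when no threshold yields instruments.
#' @export
reverse_mr <- function(outcome_as_exposure, exposure_as_outcome, ld,
                       p_thresholds = c(5e-8, 5e-6), r2_threshold = 1e-3,
                       window_bp = 1e7, palindrome_eaf_limit = 0.42) {
  for (p in p_thresholds) {
    res <- tryCatch({
      ins <- select_instruments(outcome_as_exposure, ld, p, r2_threshold,
                                window_bp)
      h <- harmonize_pair(ins$variants, exposure_as_outcome,
                          palindrome_eaf_limit)
      dispatch_mr(h)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      attr(res, "p_threshold_used") <- p
      return(res)
    }
  }
  not_evaluable(paste0("no reverse instruments at P<=",
                       paste(format(p_thresholds), collapse = " or ")))
}

#' Effective sample size of a case-control GWAS
#'
#' `N_eff = 4 n_case n_control / (n_case + n_control)` — the balanced-design
#' equivalent sample size.
#'
#' @param n_case,n_control Positive counts.
#' @return Effective sample size.
#' @export
effective_n <- function(n_case, n_control) {
  if (any(c(n_case, n_control) <= 0)) stop("counts must be positive")
  4 * n_case * n_control / (n_case + n_control)
}

#' Effective sample-size overlap fraction between two case-control GWAS
#'
#' @param n_case_1,n_control_1,n_case_2,n_control_2 Cohort counts.
#' @param n_shared_eff Effective number of shared participants; must not
#'   exceed the smaller cohort's effective size.
#' @return The overlap fraction `n_shared_eff / min(N_eff_1, N_eff_2)`, with
#'   attributes `n_eff_1`, `n_eff_2`.
#' @export
effective_overlap <- function(n_case_1, n_control_1, n_case_2, n_control_2,
                              n_shared_eff) {
  n1 <- effective_n(n_case_1, n_control_1)
  n2 <- effective_n(n_case_2, n_control_2)
  if (n_shared_eff < 0) stop("n_shared_eff must be non-negative")
  if (n_shared_eff > min(n1, n2)) {
    stop("n_shared_eff exceeds the smaller effective sample size")
  }
  structure(n_shared_eff / min(n1, n2), n_eff_1 = n1, n_eff_2 = n2)
}
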