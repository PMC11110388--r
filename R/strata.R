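#' Default age strata: children, then ten-year adult bands to over-90
#'
#' @return Numeric break vector `c(0, 16, 30, 40, ..., 90, Inf)`; bands are
#'   left-closed, right-open.
#' @export
age_bins <- function() c(0, 16, 30, 40, 50, 60, 70, 80, 90, Inf)

age_bin_labels <- function(breaks) {
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  labs <- ifelse(lo == 0, sprintf("<%g", hi),
                 ifelse(is.infinite(hi), sprintf("%g+", lo),
                        sprintf("%g-%g", lo, hi - 1)))
  labs
}

# metrics row that tolerates an empty margin (reported with counts, no estimate)
safe_metrics <- function(tp, fp, tn, fn, ci_method = "wilson") {
  base <- tibble::tibble(n = tp + fp + tn + fn, tp = tp, fp = fp, tn = tn, fn = fn)
  res <- tryCatch({
    e <- estimate_accuracy(two_by_two(tp, fp, tn, fn), ci_method = ci_method)
    tibble::tibble(
      sensitivity = e$sensitivity,
      sens_lcl = e$sensitivity_ci[["lower"]], sens_ucl = e$sensitivity_ci[["upper"]],
      specificity = e$specificity,
      spec_lcl = e$specificity_ci[["lower"]], spec_ucl = e$specificity_ci[["upper"]],
      lr_pos = e$lr_pos,
      lr_pos_lcl = e$lr_pos_ci[["lower"]], lr_pos_ucl = e$lr_pos_ci[["upper"]],
      lr_neg = e$lr_neg,
      lr_neg_lcl = e$lr_neg_ci[["lower"]], lr_neg_ucl = e$lr_neg_ci[["upper"]])
  }, triagecc_margin_error = function(e) NULL)
  if (is.null(res)) {
    # report whichever margin is estimable
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
    res <- tibble::tibble(sensitivity = sens, sens_lcl = NA_real_, sens_ucl = NA_real_,
                          specificity = spec, spec_lcl = NA_real_, spec_ucl = NA_real_,
                          lr_pos = NA_real_, lr_pos_lcl = NA_real_, lr_pos_ucl = NA_real_,
                          lr_neg = NA_real_, lr_neg_lcl = NA_real_, lr_neg_ucl = NA_real_)
  }
  dplyr::bind_cols(base, res)
}

#' Stratified diagnostic accuracy
#'
#' Computes one accuracy estimate per stratum, either over age bands
#' (numeric `strata` breaks partitioning the age axis) or over the levels
#' of a grouping column such as `service`. Counts follow the unweighted
#' case-cohort rule when `in_subcohort` is present (all cases for the
#' sensitivity margin, sub-cohort negatives for the specificity margin);
#' otherwise all records are cross-tabulated. Strata with an empty margin
#' are reported with their counts and `NA` estimates.
#'
#' @param records Analysis-set tibble with index and reference columns.
#' @param index,reference Column names of the logical index-test and
#'   reference-standard flags.
#' @param strata Numeric break vector over age (strictly increasing,
#'   covering all ages present), or the name of a categorical column.
#' @param ci_method Proportion CI method, `"wilson"` or `"wald"`.
#' @return Tibble with one row per stratum: `stratum`, counts and metrics.
#' @export
stratified_accuracy <- function(records, index, reference, strata = age_bins(),
                                ci_method = "wilson") {
  if (is.numeric(strata)) {
    if (any(diff(strata) <= 0))
      abort("age strata breaks must be strictly increasing (non-overlapping bands)",
            class = "triagecc_config_error")
    if (min(records$age_years) < strata[1] ||
        max(records$age_years) >= strata[length(strata)])
      abort("age strata do not cover the observed age range",
            class = "triagecc_config_error")
    lab <- cut(records$age_years, breaks = strata, right = FALSE,
               labels = age_bin_labels(strata))
  } else {
    lab <- factor(records[[strata]])
  }
  idx <- records[[index]]; ref <- records[[reference]]
  keep <- if ("in_subcohort" %in% names(records)) ref | records$in_subcohort
          else rep(TRUE, nrow(records))
  purrr::map_dfr(levels(lab), function(lv) {
    s <- keep & lab == lv
    dplyr::bind_cols(
      tibble::tibble(stratum = lv),
      safe_metrics(sum(idx & ref & s), sum(idx & !ref & s),
                   sum(!idx & !ref & s), sum(!idx & ref & s), ci_method))
  })
}

#' Cumulative-step accuracy series for a triage tool
#'
#' Evaluates the tool at every cumulative step depth (steps 1..k), builds
#' the per-depth 2x2 table under the unweighted case-cohort rule, and
#' returns the estimates together with the ROC point (1 - specificity,
#' sensitivity) at each depth. Because the cumulative result is monotone in
#' depth, sensitivity is non-decreasing and specificity non-increasing
#' across the series. If `index` is supplied, the observed-decision point
#' is appended for comparison (depth `NA`, labelled `"observed decision"`).
#'
#' @param records Analysis-set tibble (complete cases) with a reference
#'   column and, when using the case-cohort rule, `in_subcohort`.
#' @param tool A [triage_tool()].
#' @param reference Column name of the reference-standard flag.
#' @param index Optional column name of the observed decision flag.
#' @param ci_method Proportion CI method.
#' @return Tibble, one row per depth (plus the optional observed point):
#'   `tool`, `depth`, `label`, counts, metrics, `fpr` and `tpr`.
#' @export
cumulative_step_series <- function(records, tool, reference,
                                   index = NULL, ci_method = "wilson") {
  ev <- evaluate_tool(records, tool)
  depths <- grep("^cumulative_", names(ev))
  ref <- records[[reference]]
  keep <- if ("in_subcohort" %in% names(records)) ref | records$in_subcohort
          else rep(TRUE, nrow(records))
  service <- tool$service_label
  grouped <- tool$grouped
  rows <- purrr::map_dfr(names(ev)[depths], function(col) {
    k <- as.integer(sub("cumulative_", "", col))
    flag <- ev[[col]]
    dplyr::bind_cols(
      tibble::tibble(tool = service, depth = k,
                     label = if (grouped) sprintf("steps 1-%d", k) else "checklist"),
      safe_metrics(sum(flag & ref & keep), sum(flag & !ref & keep),
                   sum(!flag & !ref & keep), sum(!flag & ref & keep), ci_method))
  })
  if (!is.null(index)) {
    flag <- records[[index]]
    rows <- dplyr::bind_rows(rows, dplyr::bind_cols(
      tibble::tibble(tool = service, depth = NA_integer_,
                     label = "observed decision"),
      safe_metrics(sum(flag & ref & keep), sum(flag & !ref & keep),
                   sum(!flag & !ref & keep), sum(!flag & ref & keep), ci_method)))
  }
  dplyr::mutate(rows, fpr = 1 - .data$specificity, tpr = .data$sensitivity)
}
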