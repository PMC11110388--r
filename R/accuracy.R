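#' Construct a 2x2 diagnostic contingency table
#'
#' Cross-tabulates a binary index test against a binary reference standard.
#' `design` records how the table was assembled: under `"case_cohort"` the
#' reference-positive margin holds *all* cases while the negative margin
#' holds sub-cohort negatives only, so row proportions (predictive values)
#' are not interpretable without re-weighting.
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts (true positive,
#'   false positive, true negative, false negative).
#' @param design `"simple"` for a simple random sample, `"case_cohort"` for
#'   a case-enriched analysis set.
#' @return An object of class `two_by_two`.
#' @seealso [build_two_by_two()], [estimate_accuracy()]
#' @export
two_by_two <- function(tp, fp, tn, fn, design = c("simple", "case_cohort")) {
  design <- match.arg(design)
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells)))
    abort("2x2 cell counts must be non-negative integers",
          class = "triagecc_table_error")
  structure(as.list(cells), design = design, class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("2x2 table (%s design), n = %d\n", attr(x, "design"),
              x$tp + x$fp + x$tn + x$fn))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("test +", "test -"), c("ref +", "ref -")))
  print(m)
  invisible(x)
}

#' Cross-tabulate aligned index-test and reference-standard flags
#'
#' @param index_flags,reference_flags Equal-length logical vectors with no
#'   missing values (records are expected to have passed complete-case
#'   filtering first).
#' @inheritParams two_by_two
#' @return A [two_by_two()] object.
#' @examples
#' build_two_by_two(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
build_two_by_two <- function(index_flags, reference_flags, design = "simple") {
  if (length(index_flags) != length(reference_flags))
    abort("index and reference flag columns must have equal length",
          class = "triagecc_table_error")
  if (anyNA(index_flags) || anyNA(reference_flags))
    abort("flag columns contain missing values; apply the complete-case filter first",
          class = "triagecc_table_error")
  i <- as.logical(index_flags); r <- as.logical(reference_flags)
  two_by_two(tp = sum(i & r), fp = sum(i & !r),
             tn = sum(!i & !r), fn = sum(!i & r), design = design)
}

#' Assemble the unweighted case-cohort 2x2 table
#'
#' Follows the unweighted case-cohort estimator: sensitivity cells (TP/FN)
#' come from every reference-positive case in the analysis set, while
#' specificity cells (FP/TN) come from sub-cohort reference-negatives only.
#'
#' @param data Data frame of analysis-set records.
#' @param index,reference,in_subcohort Column names (strings) of the index
#'   test flag, reference standard flag and sub-cohort membership flag.
#' @return A [two_by_two()] with `design = "case_cohort"`.
#' @export
case_cohort_table <- function(data, index, reference, in_subcohort = "in_subcohort") {
  idx <- data[[index]]; ref <- data[[reference]]; sub <- data[[in_subcohort]]
  if (is.null(idx) || is.null(ref) || is.null(sub))
    abort("index/reference/in_subcohort columns not found",
          class = "triagecc_table_error")
  keep <- ref | sub          # all cases + sub-cohort negatives
  build_two_by_two(idx[keep], ref[keep], design = "case_cohort")
}

# ---- binomial proportion CIs ------------------------------------------------

ci_proportion <- function(x, n, conf_level = 0.95,
                          method = c("wilson", "wald")) {
  method <- match.arg(method)
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  if (method == "wald") {
    hw <- z * sqrt(p * (1 - p) / n)
    lo <- p - hw; hi <- p + hw
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- centre - hw; hi <- centre + hw
  }
  c(lower = max(0, lo), upper = min(1, hi))
}

# log-method (Simel) CI for a likelihood ratio; 0.5 continuity correction is
# applied to the interval (never the point estimate) when a cell is empty
ci_likelihood_ratio <- function(num_events, num_total, den_events, den_total,
                                lr, conf_level = 0.95) {
  if (is.na(lr) || lr <= 0) return(c(lower = NA_real_, upper = NA_real_))
  a <- num_events; b <- den_events
  corr <- a == 0 || b == 0 || a == num_total || b == den_total
  if (corr) { a <- a + 0.5; b <- b + 0.5
              nt <- num_total + 1; dt <- den_total + 1 } else {
              nt <- num_total; dt <- den_total }
  se <- sqrt(1 / a - 1 / nt + 1 / b - 1 / dt)
  z <- qnorm(1 - (1 - conf_level) / 2)
  lr_c <- if (corr) (a / nt) / (b / dt) else lr
  c(lower = lr_c * exp(-z * se), upper = lr_c * exp(z * se))
}

#' Estimate diagnostic accuracy from a 2x2 table
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, the
#' positive likelihood ratio `sens/(1-spec)` and negative likelihood ratio
#' `(1-sens)/spec`, each with a 95% (by default) confidence interval.
#' Proportion intervals use the Wilson score method by default (Wald
#' available); likelihood-ratio intervals use the log-transform method.
#' When specificity is exactly 1 the positive likelihood ratio is reported
#' as `Inf` with a continuity-corrected one-sided interval and the estimate
#' is flagged.
#'
#' @param t A [two_by_two()] object.
#' @param ci_method `"wilson"` (default) or `"wald"` for the proportion CIs.
#' @param conf_level Confidence level, default 0.95.
#' @param stratum Optional label carried through to tidied output.
#' @return An object of class `accuracy_estimate`; see [tidy.accuracy_estimate()]
#'   and [glance.accuracy_estimate()].
#' @examples
#' t <- two_by_two(tp = 446, fp = 95, tn = 1703, fn = 513)
#' est <- estimate_accuracy(t)
#' glance(est)
#' @export
estimate_accuracy <- function(t, ci_method = c("wilson", "wald"),
                              conf_level = 0.95, stratum = NA_character_) {
  stopifnot(inherits(t, "two_by_two"))
  ci_method <- match.arg(ci_method)
  pos <- t$tp + t$fn; neg <- t$fp + t$tn
  if (pos == 0)
    abort("sensitivity undefined: reference-positive margin (tp + fn) is empty",
          class = "triagecc_margin_error")
  if (neg == 0)
    abort("specificity undefined: reference-negative margin (fp + tn) is empty",
          class = "triagecc_margin_error")
  sens <- t$tp / pos
  spec <- t$tn / neg
  lr_pos <- if (spec < 1) sens / (1 - spec) else Inf
  lr_neg <- if (spec > 0) (1 - sens) / spec else Inf
  structure(list(
    tp = t$tp, fp = t$fp, tn = t$tn, fn = t$fn, n = pos + neg,
    sensitivity = sens, sensitivity_ci = ci_proportion(t$tp, pos, conf_level, ci_method),
    specificity = spec, specificity_ci = ci_proportion(t$tn, neg, conf_level, ci_method),
    lr_pos = lr_pos,
    lr_pos_ci = ci_likelihood_ratio(t$tp, pos, t$fp, neg, lr_pos, conf_level),
    lr_neg = lr_neg,
    lr_neg_ci = ci_likelihood_ratio(t$fn, pos, t$tn, neg, lr_neg, conf_level),
    lr_pos_infinite = !is.finite(lr_pos),
    ci_method = ci_method, conf_level = conf_level,
    stratum = stratum, design = attr(t, "design")
  ), class = "accuracy_estimate")
}

#' Predictive values from a 2x2 table
#'
#' Direct row proportions `PPV = TP/(TP+FP)` and `NPV = TN/(TN+FN)`. Under a
#' case-enriched (case-cohort) analysis set these are inflated relative to
#' the source population and a warning is issued; use
#' [posttest_probability()] with the sub-cohort prevalence instead.
#'
#' @inheritParams estimate_accuracy
#' @return Named numeric vector `c(ppv, npv)`.
#' @export
predictive_values <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  if (identical(attr(t, "design"), "case_cohort"))
    warn(paste("predictive values from a case-cohort table are inflated by",
               "case enrichment; combine likelihood ratios with the sub-cohort",
               "prevalence via posttest_probability() instead"),
         class = "triagecc_ppv_warning")
  c(ppv = t$tp / (t$tp + t$fp), npv = t$tn / (t$tn + t$fn))
}

#' Estimate reference-standard prevalence from the random sub-cohort
#'
#' An unweighted simple proportion with a binomial confidence interval.
#' Only sub-cohort records may be used: cases recruited from outside the
#' sub-cohort would inflate the estimate.
#'
#' @param positive_flags Logical vector of reference-standard status for
#'   sub-cohort records, or a single count of positives if `n` is given.
#' @param n Optional denominator when `positive_flags` is a count.
#' @param ci_method `"wald"` (default, matching conventional reporting) or
#'   `"wilson"`.
#' @param conf_level Confidence level.
#' @return One-row tibble: `prevalence`, `conf.low`, `conf.high`, `positives`, `n`.
#' @examples
#' estimate_prevalence(54, n = 1722) # 3.1%
#' @export
estimate_prevalence <- function(positive_flags, n = NULL,
                                ci_method = c("wald", "wilson"),
                                conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (is.null(n)) {
    if (anyNA(positive_flags))
      abort("missing values in sub-cohort status flags", class = "triagecc_table_error")
    x <- sum(positive_flags); n <- length(positive_flags)
  } else {
    x <- positive_flags
  }
  if (n == 0) abort("empty sub-cohort: prevalence undefined",
                    class = "triagecc_margin_error")
  ci <- ci_proportion(x, n, conf_level, ci_method)
  tibble::tibble(prevalence = x / n, conf.low = ci[["lower"]],
                 conf.high = ci[["upper"]], positives = x, n = n)
}

#' Post-test probability from pre-test prevalence and a likelihood ratio
#'
#' Bayes' theorem on the odds scale: pre-test odds `p/(1-p)` are multiplied
#' by the likelihood ratio and converted back to a probability. With the
#' positive likelihood ratio this gives the probability of disease after a
#' positive test; with the negative likelihood ratio, after a negative test
#' (its complement is the probability of *no* disease after a negative test).
#'
#' @param prevalence Pre-test probability, strictly inside (0, 1).
#' @param lr Positive likelihood ratio value (> 0). Vectorised.
#' @return Post-test probability in `[0, 1)`.
#' @examples
#' posttest_probability(0.031, 8.80)  # ~0.22 after a positive triage decision
#' 1 - posttest_probability(0.031, 0.56)  # ~0.98 chance of no major trauma
#' @export
posttest_probability <- function(prevalence, lr) {
  if (any(!is.finite(prevalence)) || any(prevalence <= 0) || any(prevalence >= 1))
    abort("`prevalence` must lie strictly in (0, 1)", class = "triagecc_config_error")
  if (any(is.na(lr)) || any(lr <= 0))
    abort("`lr` must be a positive likelihood ratio", class = "triagecc_config_error")
  odds <- prevalence / (1 - prevalence) * lr
  odds / (1 + odds)
}

#' Recompute accuracy metrics from a table of published 2x2 counts
#'
#' Takes a counts table (columns `tp`, `fp`, `tn`, `fn`, plus any label
#' columns such as `tool_name`) and appends point estimates and confidence
#' intervals for sensitivity, specificity and both likelihood ratios, one
#' row per input row. This is the entry point for re-deriving every metric
#' of a published accuracy table from its printed contingency cells.
#'
#' @param counts Data frame with integer columns `tp`, `fp`, `tn`, `fn`.
#' @inheritParams estimate_accuracy
#' @return The input tibble with metric columns appended (full precision;
#'   apply [round_half_up()] for presentation).
#' @examples
#' accuracy_from_counts(data.frame(tp = 446, fp = 95, tn = 1703, fn = 513))
#' @export
accuracy_from_counts <- function(counts, ci_method = c("wilson", "wald"),
                                 conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  need <- c("tp", "fp", "tn", "fn")
  if (!all(need %in% names(counts)))
    abort("`counts` must contain columns tp, fp, tn, fn",
          class = "triagecc_table_error")
  est <- purrr::pmap(counts[need], function(tp, fp, tn, fn) {
    e <- estimate_accuracy(two_by_two(tp, fp, tn, fn),
                           ci_method = ci_method, conf_level = conf_level)
    tibble::tibble(
      sensitivity = e$sensitivity,
      sens_lcl = e$sensitivity_ci[["lower"]], sens_ucl = e$sensitivity_ci[["upper"]],
      specificity = e$specificity,
      spec_lcl = e$specificity_ci[["lower"]], spec_ucl = e$specificity_ci[["upper"]],
      lr_pos = e$lr_pos,
      lr_pos_lcl = e$lr_pos_ci[["lower"]], lr_pos_ucl = e$lr_pos_ci[["upper"]],
      lr_neg = e$lr_neg,
      lr_neg_lcl = e$lr_neg_ci[["lower"]], lr_neg_ucl = e$lr_neg_ci[["upper"]])
  })
  dplyr::bind_cols(tibble::as_tibble(counts), dplyr::bind_rows(est))
}

#' Path to the bundled published triage-accuracy counts fixture
#'
#' Contingency-table counts (and the metrics printed alongside them) for
#' eighteen index tests — cumulative triage-tool steps and observed provider
#' decisions, per ambulance service and pooled — as reported by a published
#' multicentre English trauma-network accuracy evaluation. Shipped so the
#' estimator can be regression-checked against an independent published
#' table and so `run_pipeline()` can consume external counts directly.
#'
#' @return File path of the CSV.
#' @export
triage_counts_path <- function() {
  system.file("extdata", "triage_counts.csv", package = "triagecc",
              mustWork = TRUE)
}
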