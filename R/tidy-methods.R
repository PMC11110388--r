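#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an accuracy estimate into one row per metric
#'
#' @param x An `accuracy_estimate` from [estimate_accuracy()].
#' @param ... Unused.
#' @return Tibble with columns `metric`, `estimate`, `conf.low`,
#'   `conf.high` for sensitivity, specificity and both likelihood ratios.
#' @method tidy accuracy_estimate
#' @export
tidy.accuracy_estimate <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "specificity", "lr_pos", "lr_neg"),
    estimate = c(x$sensitivity, x$specificity, x$lr_pos, x$lr_neg),
    conf.low = c(x$sensitivity_ci[["lower"]], x$specificity_ci[["lower"]],
                 x$lr_pos_ci[["lower"]], x$lr_neg_ci[["lower"]]),
    conf.high = c(x$sensitivity_ci[["upper"]], x$specificity_ci[["upper"]],
                  x$lr_pos_ci[["upper"]], x$lr_neg_ci[["upper"]]))
}

#' One-row summary of an accuracy estimate
#'
#' @param x An `accuracy_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the 2x2 counts, point estimates, CI method
#'   and design.
#' @method glance accuracy_estimate
#' @export
glance.accuracy_estimate <- function(x, ...) {
  tibble::tibble(n = x$n, tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 lr_pos = x$lr_pos, lr_neg = x$lr_neg,
                 ci_method = x$ci_method, conf_level = x$conf_level,
                 design = x$design, stratum = x$stratum)
}

#' @export
print.accuracy_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("Diagnostic accuracy (n = %d, %s design, %s %.0f%% CI)\n",
              x$n, x$design, x$ci_method, 100 * x$conf_level))
  fmt <- function(est, ci) sprintf("%.*f (%.*f-%.*f)", digits,
                                   round_half_up(est, digits), digits,
                                   round_half_up(ci[["lower"]], digits), digits,
                                   round_half_up(ci[["upper"]], digits))
  cat("  sensitivity:", fmt(x$sensitivity, x$sensitivity_ci), "\n")
  cat("  specificity:", fmt(x$specificity, x$specificity_ci), "\n")
  cat("  LR+:        ", if (is.finite(x$lr_pos)) fmt(x$lr_pos, x$lr_pos_ci)
      else sprintf("Inf (lower %.2f)", x$lr_pos_ci[["lower"]]), "\n")
  cat("  LR-:        ", fmt(x$lr_neg, x$lr_neg_ci), "\n")
  invisible(x)
}
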