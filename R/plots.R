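#' ROC-style plot of cumulative triage-tool steps and observed decisions
#'
#' Plots each tool's cumulative-step series in (1 - specificity,
#' sensitivity) space, connected in depth order, with observed-decision
#' points (if present) drawn as open triangles.
#'
#' @param series Tibble from [cumulative_step_series()], or several bound
#'   together with `dplyr::bind_rows()`.
#' @return A ggplot object.
#' @export
plot_step_roc <- function(series) {
  steps <- dplyr::filter(series, !is.na(.data$depth))
  obs <- dplyr::filter(series, is.na(.data$depth))
  p <- ggplot2::ggplot(steps, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                           colour = .data$tool)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", colour = "tool",
                  title = "Cumulative triage-tool steps vs observed decisions") +
    ggplot2::theme_minimal()
  if (nrow(obs) > 0)
    p <- p + ggplot2::geom_point(data = obs, shape = 2, size = 3)
  p
}

#' Accuracy of observed decisions across age strata
#'
#' Paired sensitivity/specificity per age band with CI ribbons, showing the
#' age trend (sensitivity falling and specificity rising towards older
#' ages).
#'
#' @param strata_tbl Tibble from [stratified_accuracy()] over age bands.
#' @return A ggplot object.
#' @export
plot_age_accuracy <- function(strata_tbl) {
  long <- dplyr::bind_rows(
    dplyr::transmute(strata_tbl, stratum = .data$stratum, metric = "sensitivity",
                     estimate = .data$sensitivity, lcl = .data$sens_lcl,
                     ucl = .data$sens_ucl),
    dplyr::transmute(strata_tbl, stratum = .data$stratum, metric = "specificity",
                     estimate = .data$specificity, lcl = .data$spec_lcl,
                     ucl = .data$spec_ucl))
  long$stratum <- factor(long$stratum, levels = unique(strata_tbl$stratum))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$estimate,
                                     colour = .data$metric,
                                     group = .data$metric)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lcl, ymax = .data$ucl),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "age group (years)", y = "estimate",
                  title = "Observed triage-decision accuracy by age group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an accuracy estimate with its confidence intervals
#'
#' @param object An `accuracy_estimate`.
#' @param ... Unused.
#' @return A ggplot object showing each metric and its CI.
#' @method autoplot accuracy_estimate
#' @export
autoplot.accuracy_estimate <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::filter(d, is.finite(.data$estimate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = NULL, y = "estimate (95% CI)") +
    ggplot2::theme_minimal()
}
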