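#' Plot the 2 x 2 stay-probability pattern
#'
#' Bar chart of mean stay probability by previous reward and transition
#' type, the standard diagnostic figure for this task: parallel bars across
#' transition indicate model-free behaviour, a crossover indicates
#' model-based behaviour.
#'
#' @param x A trial-record tibble, encoded rows, or the output of
#'   [stay_probability_summary()].
#' @return A ggplot object.
#' @export
plot_stay_probability <- function(x) {
  tab <- if (all(c("rewarded", "transition", "stay_prob") %in% names(x))) {
    x
  } else {
    stay_probability_summary(x)
  }
  tab$rewarded <- factor(ifelse(tab$rewarded, "rewarded", "unrewarded"),
                         levels = c("rewarded", "unrewarded"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$rewarded, y = .data$stay_prob,
                                    fill = .data$transition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$stay_prob - .data$se,
                   ymax = .data$stay_prob + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = "previous trial outcome", y = "stay probability",
                  fill = "transition") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient plot for a multilevel stay/switch fit
#'
#' Forest plot of the fixed effects with 95% Wald intervals.
#'
#' @param object A `twostep_glmm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.twostep_glmm <- function(object, ...) {
  fx <- object$fixed
  fx$term <- factor(fx$term, levels = rev(fx$term))
  ggplot2::ggplot(fx, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                   xmax = .data$estimate + 1.96 * .data$se)
    ) +
    ggplot2::labs(x = "estimate (log-odds)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of engagement scores
#'
#' @param object An `engagement_table`.
#' @param ... Unused.
#' @return A ggplot object with the top-fraction subjects highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.engagement_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score,
                                       fill = .data$in_top_fraction)) +
    ggplot2::geom_histogram(bins = 30, colour = "white") +
    ggplot2::labs(x = "engagement score (deviance difference)", y = "subjects",
                  fill = "top fraction") +
    ggplot2::theme_minimal()
}
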