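#' Volcano-style plot of a moderated fit
#'
#' Delta beta against -log10 p, coloured by MVP call when available.
#'
#' @param object A `moderated_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.moderated_fit <- function(object, ...) {
  tab <- tidy(object)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$delta_beta,
                                         y = -log10(.data$p)))
  if ("significant" %in% names(tab))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                                 alpha = 0.5, size = 0.8) +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                              `FALSE` = "grey60"))
  else p <- p + ggplot2::geom_point(alpha = 0.5, size = 0.8)
  p + ggplot2::labs(x = expression(Delta * beta~(HDC - LDC)),
                    y = expression(-log[10]~p))
}

#' Group means with confidence intervals
#'
#' Line-level mean methylation by group, with each group's mean and t-based
#' confidence interval.
#'
#' @param object A `group_delta`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.group_delta <- function(object, ...) {
  ggplot2::ggplot(object$line_means,
                  ggplot2::aes(x = .data$group, y = .data$mean_beta)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::geom_pointrange(data = object$group_summary,
                             ggplot2::aes(y = .data$mean, ymin = .data$ci_lower,
                                          ymax = .data$ci_upper),
                             colour = "#2166ac", fatten = 2) +
    ggplot2::labs(x = NULL, y = expression(beta[mean]))
}

#' Deviation-from-threshold bar plot of capacity predictions
#'
#' One signed bar per line: panel mean minus the decision threshold,
#' coloured by the predicted class (positive bars predict HDC).
#'
#' @param predictions Output of [predict_capacity()].
#' @return A ggplot object.
#' @export
plot_deviations <- function(predictions) {
  dat <- predictions %>% arrange(dplyr::desc(.data$deviation)) %>%
    mutate(line_id = factor(.data$line_id, .data$line_id))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$line_id, y = .data$deviation,
                                    fill = .data$predicted)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(HDC = "#1b7837", LDC = "#b2182b"),
                               na.value = "grey70") +
    ggplot2::labs(x = NULL, y = "panel mean - threshold") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
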