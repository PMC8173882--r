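#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_line geom_errorbarh geom_linerange labs theme_minimal
#'   scale_y_continuous
NULL

#' Plot the cost-effectiveness plane
#'
#' Scatter of per-iteration incremental QALYs (x) against incremental cost
#' (y) relative to the comparator, with the origin marked. Points in the
#' lower-right quadrant are both cheaper and more effective.
#'
#' @param object A `feno_ce_plane` from [ce_plane_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feno_ce_plane <- function(object, ...) {
  ggplot(object$increments, aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_hline(yintercept = 0, linetype = 2) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "Incremental QALYs", y = "Incremental cost (US$)",
         title = sprintf("Cost-effectiveness plane vs %s", object$comparator)) +
    theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `feno_ceac` from [ceac()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feno_ceac <- function(object, ...) {
  ggplot(object, aes(x = .data$wtp, y = .data$probability,
                     colour = .data$strategy)) +
    geom_line() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Willingness to pay (US$/QALY)",
         y = "Probability of maximal net benefit",
         colour = "Strategy", title = "Acceptability curve") +
    theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning the outcome at the low and high bound of each
#' one-way sweep, widest swing on top.
#'
#' @param object A `feno_tornado` from [tornado_table()].
#' @param top Show only the `top` widest bars (default 12).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feno_tornado <- function(object, top = 12, ...) {
  df <- utils::head(as.data.frame(object), top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot(df, aes(y = .data$parameter)) +
    geom_linerange(aes(xmin = pmin(.data$outcome_low, .data$outcome_high),
                       xmax = pmax(.data$outcome_low, .data$outcome_high)),
                   linewidth = 4, colour = "steelblue") +
    labs(x = sprintf("Incremental outcome (%s)", attr(object, "outcome")),
         y = NULL, title = "Tornado diagram") +
    theme_minimal()
}

#' Plot a forest of study effects
#'
#' @param object A `feno_meta` from [dl_pool()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feno_meta <- function(object, ...) {
  df <- forest_table(object)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot(df, aes(x = .data$rr, y = .data$label)) +
    geom_point(aes(size = .data$weight_pct), shape = 15, show.legend = FALSE) +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_vline(xintercept = 1, linetype = 2) +
    labs(x = "Relative risk (log scale)", y = NULL,
         title = "Random-effects pooling") +
    ggplot2::scale_x_log10() +
    theme_minimal()
}
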