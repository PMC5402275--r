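#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a waveform segment
#'
#' @param object a [waveform()] tibble.
#' @param from_s,to_s time range to draw (defaults to the first 10 s).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.wave_tbl <- function(object, from_s = NULL, to_s = NULL, ...) {
  if (is.null(from_s)) from_s <- object$time_s[1]
  if (is.null(to_s)) to_s <- min(from_s + 10, max(object$time_s))
  seg <- dplyr::filter(tibble::as_tibble(object),
                       .data$time_s >= from_s, .data$time_s <= to_s)
  ggplot2::ggplot(seg, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("%s (%s)", wave_channel(object),
                              wave_units(object))) +
    ggplot2::theme_minimal()
}

#' Log-log fluctuation plot of a DFA result
#'
#' F(n) against box size on log10 axes with the two fitted scaling
#' ranges overlaid.
#'
#' @param object a `dfa_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dfa_result <- function(object, ...) {
  df <- object$fluctuations
  p <- ggplot2::ggplot(df, ggplot2::aes(log10(.data$n), log10(.data$F))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "log10 box size (events)",
                  y = "log10 F(n)") +
    ggplot2::theme_minimal()
  if (!object$degenerate) {
    seg <- function(rng, alpha) {
      d <- df[df$n >= rng[1] & df$n <= rng[2], ]
      lx <- log10(d$n); ly <- log10(d$F)
      int <- mean(ly) - alpha * mean(lx)
      tibble::tibble(x = range(lx), y = int + alpha * range(lx))
    }
    s1 <- seg(object$range1, object$alpha1)
    s2 <- seg(object$range2, object$alpha2)
    p <- p +
      ggplot2::geom_line(data = s1, ggplot2::aes(.data$x, .data$y),
                         colour = "#D55E00") +
      ggplot2::geom_line(data = s2, ggplot2::aes(.data$x, .data$y),
                         colour = "#0072B2") +
      ggplot2::labs(subtitle = sprintf("alpha1 = %.2f, alpha2 = %.2f",
                                       object$alpha1, object$alpha2))
  }
  p
}

#' ROC curve plot
#'
#' @param object a `roc_delong`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roc_delong <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC %.3f (%.3f, %.3f)",
                                     object$auc, object$ci[1],
                                     object$ci[2])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.roc_delong
#' @export
autoplot.ivh_model <- function(object, ...) autoplot(object$roc, ...)

#' Plot a per-window probability trace
#'
#' @param trace tibble from [monitor_probability()].
#' @param threshold optional decision threshold drawn as a dashed line.
#' @return a ggplot.
#' @export
plot_probability_trace <- function(trace, threshold = NULL) {
  p <- ggplot2::ggplot(trace,
                       ggplot2::aes(.data$window_start_s / 60,
                                    .data$probability)) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "window start (min)",
                  y = "predicted IVH probability") +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  p
}
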