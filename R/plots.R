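#' Plot a decoding time course
#'
#' Group-mean accuracy over time with the chance level, a band of +/- 1
#' standard error across subjects, and dots marking Bonferroni-significant
#' time points (when [group_stats] has been run).
#'
#' @param object A [decoding_result].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoding_result <- function(object, ...) {
  gm <- colMeans(object$accuracy)
  se <- apply(object$accuracy, 2, stats::sd) / sqrt(nrow(object$accuracy))
  df <- tibble::tibble(time = object$times, accuracy = gm, se = se)
  chance <- if (is.null(object$chance)) 50 else object$chance
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$accuracy)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$accuracy - .data$se,
                   ymax = .data$accuracy + .data$se),
      alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "decoding accuracy (%)")
  if (!is.null(object$stats) && any(object$stats$significant)) {
    sig <- df[object$stats$significant, ]
    p <- p + ggplot2::geom_point(data = sig, colour = "firebrick", size = 1)
  }
  p
}

#' Plot the lagged connectivity weights of an MVAR fit
#'
#' Heatmap of source -> target lagged weights, faceted by lag.
#'
#' @param object An `mvar_fit`.
#' @param lags Lags to show (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mvar_fit <- function(object, lags = seq_len(object$order), ...) {
  df <- tidy(object)
  df <- df[df$term == "lagged_source" & df$lag %in% lags, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$target,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~lag, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "source region", y = "target region") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot a motor ERP report
#'
#' Group-mean contralateral-minus-ipsilateral difference waves for the
#' actual (and, when present, predicted) data, with significant time points
#' marked.
#'
#' @param object An `erp_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.erp_report <- function(object, ...) {
  df <- dplyr::mutate(object$diff_stats, data = "actual")
  if (!is.null(object$predicted_diff_stats)) {
    df <- dplyr::bind_rows(
      df, dplyr::mutate(object$predicted_diff_stats, data = "predicted"))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time,
                                        y = .data$mean_amplitude,
                                        colour = .data$data)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "contra - ipsi amplitude (a.u.)",
                  colour = NULL)
  sig <- df[df$significant, ]
  if (nrow(sig)) p <- p + ggplot2::geom_point(data = sig, size = 1)
  p
}

#' @importFrom rlang .data
NULL
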