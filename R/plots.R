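#' Plot a fitted shrinker
#'
#' Observed count against shrunk relative reporting ratio (EBGM), log-log,
#' with the EB05 flagging status coloured when a threshold is set.
#'
#' @param object An `mgps_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mgps_fit <- function(object, ...) {
  d <- object$results
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$ebgm)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "observed reports (N)",
                  y = "EBGM (shrunk relative reporting ratio)",
                  title = object$label %||% object$spec$label)
  if (!is.null(d$flagged)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$flagged), alpha = 0.6) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                              `TRUE` = "firebrick"))
  } else {
    p + ggplot2::geom_point(alpha = 0.6)
  }
}

#' Plot a time-to-onset scan
#'
#' The two background KS p-values per pair (log scales), with the
#' dual-significance flagging region in the lower-left corner.
#'
#' @param object A `tto_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tto_scan <- function(object, ...) {
  d <- object$results[object$results$status == "OK", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = pmax(.data$p_events, 1e-16),
                                  y = pmax(.data$p_vaccines, 1e-16),
                                  colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "p (between events)", y = "p (between vaccines)",
                  title = object$label)
}

#' Plot one or more ROC curves
#'
#' @param object A `roc_curve` tibble, or a named list of them (one curve
#'   per algorithm family).
#' @param ... Unused.
#' @return A ggplot of sensitivity against 1 - specificity.
#' @export
autoplot.roc_curve <- function(object, ...) plot_roc(list(ROC = object))

#' @rdname autoplot.roc_curve
#' @param curves A named list of `roc_curve` tibbles.
#' @export
plot_roc <- function(curves) {
  d <- dplyr::bind_rows(lapply(curves, tibble::as_tibble), .id = "curve")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$one_minus_specificity,
                                  y = .data$sensitivity,
                                  colour = .data$curve)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", colour = NULL)
}
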