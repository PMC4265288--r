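#' Tidy per-pair results of a fitted shrinker
#'
#' @param x An `mgps_fit` from [run_mgps()].
#' @param ... Unused.
#' @return The per-pair results tibble (`vaccine`, `event`, `n`, `expected`,
#'   `q`, `ebgm`, `eb05`, `eb95`, and `flagged` when thresholded).
#' @export
tidy.mgps_fit <- function(x, ...) x$results

#' One-row summary of a fitted shrinker
#'
#' @param x An `mgps_fit`.
#' @param ... Unused.
#' @return A one-row tibble: prior parameters, marginal log-likelihood,
#'   convergence, pair count, stratification and threshold.
#' @export
glance.mgps_fit <- function(x, ...) {
  p <- x$prior
  tibble::tibble(alpha1 = p$alpha1, beta1 = p$beta1, alpha2 = p$alpha2,
                 beta2 = p$beta2, P = p$P, loglik = p$loglik,
                 converged = p$converged, n_pairs = nrow(x$results),
                 stratification = x$spec$label,
                 threshold = x$threshold %||% NA_real_,
                 n_flagged = if (is.null(x$results$flagged)) NA_integer_
                             else sum(x$results$flagged))
}

#' @rdname glance.mgps_fit
#' @param x A `gps_prior`.
#' @export
tidy.gps_prior <- function(x, ...) {
  tibble::tibble(term = c("alpha1", "beta1", "alpha2", "beta2", "P"),
                 estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$P))
}

#' Tidy per-pair results of a time-to-onset scan
#'
#' @param x A `tto_scan`.
#' @param ... Unused.
#' @return The per-pair results tibble.
#' @export
tidy.tto_scan <- function(x, ...) x$results

#' One-row summary of a time-to-onset scan
#'
#' @param x A `tto_scan`.
#' @param ... Unused.
#' @return A one-row tibble: configuration, pair counts by status, flags.
#' @export
glance.tto_scan <- function(x, ...) {
  r <- x$results
  tibble::tibble(label = x$label, alpha = x$alpha,
                 window_days = x$window_days, min_target = x$min_target,
                 n_pairs = nrow(r), n_testable = sum(r$status == "OK"),
                 n_flagged = sum(r$flagged))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
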