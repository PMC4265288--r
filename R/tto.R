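#' Two-sample Kolmogorov-Smirnov test with ties
#'
#' Computes the sup-distance between the empirical CDFs of two samples,
#' evaluated at every pooled observed value (so heavily tied integer-day data
#' are handled by the standard ties convention), and a p-value from the
#' asymptotic Kolmogorov distribution of \eqn{D\sqrt{n_x n_y/(n_x+n_y)}}.
#' With `exact = TRUE` and `n_x * n_y <= 10000` the exact conditional null
#' distribution given the tie pattern is used instead (via
#' [stats::psmirnov()]).  The asymptotic p-value is conservative under ties,
#' which suits a screening test.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact Use the exact small-sample p-value when feasible.
#' @return A list with `statistic` (D), `p_value`, `n_x`, `n_y`.
#' @export
#' @examples
#' ks_two_sample(c(1, 2, 3), c(1, 2, 3, 10))  # D = 0.25
ks_two_sample <- function(x, y, exact = FALSE) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pooled <- sort(unique(c(x, y)))
  d_all <- abs(stats::ecdf(x)(pooled) - stats::ecdf(y)(pooled))
  D <- max(d_all)
  n_x <- length(x); n_y <- length(y)
  if (exact && n_x * n_y <= 10000) {
    p <- 1 - stats::psmirnov(D, sizes = c(n_x, n_y), z = sort(c(x, y)),
                             two.sided = TRUE, exact = TRUE)
  } else {
    p <- kolmogorov_tail(D * sqrt(n_x * n_y / (n_x + n_y)))
  }
  list(statistic = D, p_value = min(max(p, 0), 1), n_x = n_x, n_y = n_y)
}

## P(K > t) for the Kolmogorov distribution; series switched at t = 1 for
## numerical accuracy at both ends.
kolmogorov_tail <- function(t) {
  if (t <= 0) return(1)
  if (t < 1) {
    k <- 1:10
    s <- sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * t^2)))
    return(1 - sqrt(2 * pi) / t * s)
  }
  k <- 1:100
  2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
}

## in-window onset delays: non-missing and 0 <= tto <= window (both ends in)
in_window <- function(reports, window_days) {
  keep <- !is.na(reports$tto_days) & reports$tto_days >= 0 &
    reports$tto_days <= window_days
  reports[keep, , drop = FALSE]
}

#' Time-to-onset sample of a vaccine-event pair
#'
#' The onset delays (days) of the pair's reports that carry a non-missing
#' time-to-onset inside the window `[0, window_days]` (both ends included).
#'
#' @param reports A reports tibble.
#' @param vaccine,event The pair of interest.
#' @param window_days Window length in days (the grid uses 30, 60, 90).
#' @return Integer vector of onset delays (possibly empty).
#' @export
tto_sample <- function(reports, vaccine, event, window_days) {
  w <- in_window(reports, window_days)
  w$tto_days[w$vaccine == vaccine & w$event == event]
}

#' Background time-to-onset samples for a pair
#'
#' The two reference distributions against which a pair's onset delays are
#' compared: `between_events` pools the in-window delays of the same vaccine
#' with *other* events, and `between_vaccines` those of the same event after
#' *other* vaccines (the vaccine of interest is excluded).  The target pair's
#' own reports appear in neither background.
#'
#' @inheritParams tto_sample
#' @return A list with integer vectors `between_events` and
#'   `between_vaccines`.
#' @export
tto_backgrounds <- function(reports, vaccine, event, window_days) {
  w <- in_window(reports, window_days)
  list(
    between_events = w$tto_days[w$vaccine == vaccine & w$event != event],
    between_vaccines = w$tto_days[w$event == event & w$vaccine != vaccine])
}

#' The 18-configuration time-to-onset grid
#'
#' Crosses six significance levels (0.01, 0.05, 0.10, 0.20, 0.50, 0.99) with
#' three windows (30, 60, 90 days).  Labels encode alpha as hundredths and
#' the window in days, e.g. `"TTO-01-60"`.
#'
#' @return A tibble with columns `label`, `alpha`, `window_days` (18 rows).
#' @export
tto_grid <- function() {
  g <- tidyr::expand_grid(alpha = c(0.01, 0.05, 0.10, 0.20, 0.50, 0.99),
                          window_days = c(30L, 60L, 90L))
  tibble::tibble(
    label = sprintf("TTO-%02d-%d", round(g$alpha * 100), g$window_days),
    alpha = g$alpha, window_days = g$window_days)
}

#' Screen all reported pairs with the time-to-onset detector
#'
#' For every reported vaccine-event pair, compares its in-window onset-delay
#' distribution against both backgrounds with two-sample Kolmogorov-Smirnov
#' tests.  A pair is flagged when both tests are significant at `alpha`
#' (per-test, no multiplicity correction -- the benchmark sweeps raw alpha
#' levels).  Pairs with too few in-window target delays or an empty
#' background get a `status` of `"INSUFFICIENT_TARGET"` /
#' `"INSUFFICIENT_BACKGROUND"` and are never flagged.
#'
#' @param reports A reports tibble.
#' @param alpha Per-test significance level.
#' @param window_days Window length in days.
#' @param min_target Minimum number of in-window target delays required
#'   (default 1; raise to e.g. 10 as a small-sample guard).
#' @param exact Passed to [ks_two_sample()].
#' @param pairs Optional tibble of `vaccine`, `event` restricting which pairs
#'   are tested; default all reported pairs.
#' @return An object of class `tto_scan`: list with `results` (tibble
#'   `vaccine`, `event`, `n_target`, `n_bg_events`, `n_bg_vaccines`,
#'   `D_events`, `p_events`, `D_vaccines`, `p_vaccines`, `status`, `flagged`)
#'   and the configuration (`alpha`, `window_days`, `min_target`, `label`).
#' @seealso [tto_flag_pair()] for a single pair, [tto_grid()]
#' @export
tto_scan <- function(reports, alpha = 0.05, window_days = 30L, min_target = 1L,
                     exact = FALSE, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- dplyr::distinct(reports[c("vaccine", "event")])
  }
  w <- in_window(reports, window_days)
  # nested split: per vaccine, a named list of per-event delay vectors
  by_vaccine <- split(w[c("event", "tto_days")], w$vaccine)
  by_vaccine <- lapply(by_vaccine, function(d) split(d$tto_days, d$event))
  by_event <- split(w[c("vaccine", "tto_days")], w$event)
  by_event <- lapply(by_event, function(d) split(d$tto_days, d$vaccine))

  k <- nrow(pairs)
  n_target <- n_bg_e <- n_bg_v <- integer(k)
  D_e <- p_e <- D_v <- p_v <- rep(NA_real_, k)
  status <- character(k)
  min_target <- max(1L, min_target)

  for (i in seq_len(k)) {
    v <- pairs$vaccine[i]; e <- pairs$event[i]
    ve <- by_vaccine[[v]]
    ev <- by_event[[e]]
    target <- if (!is.null(ve)) ve[[e]] else NULL
    if (is.null(target)) target <- integer(0)
    bg_e <- unlist(ve[setdiff(names(ve), e)], use.names = FALSE)
    if (is.null(bg_e)) bg_e <- integer(0)
    bg_v <- unlist(ev[setdiff(names(ev), v)], use.names = FALSE)
    if (is.null(bg_v)) bg_v <- integer(0)
    n_target[i] <- length(target)
    n_bg_e[i] <- length(bg_e)
    n_bg_v[i] <- length(bg_v)
    if (length(target) < min_target) {
      status[i] <- "INSUFFICIENT_TARGET"
    } else if (length(bg_e) == 0 || length(bg_v) == 0) {
      status[i] <- "INSUFFICIENT_BACKGROUND"
    } else {
      status[i] <- "OK"
      ks1 <- ks_two_sample(target, bg_e, exact = exact)
      ks2 <- ks_two_sample(target, bg_v, exact = exact)
      D_e[i] <- ks1$statistic; p_e[i] <- ks1$p_value
      D_v[i] <- ks2$statistic; p_v[i] <- ks2$p_value
    }
  }
  results <- tibble::tibble(
    vaccine = pairs$vaccine, event = pairs$event,
    n_target = n_target, n_bg_events = n_bg_e, n_bg_vaccines = n_bg_v,
    D_events = D_e, p_events = p_e, D_vaccines = D_v, p_vaccines = p_v,
    status = status,
    flagged = status == "OK" & !is.na(p_e) & !is.na(p_v) &
      p_e < alpha & p_v < alpha)
  structure(list(results = results, alpha = alpha,
                 window_days = as.integer(window_days),
                 min_target = min_target,
                 label = sprintf("TTO-%02d-%d", round(alpha * 100),
                                 as.integer(window_days))),
            class = "tto_scan")
}

#' Test a single vaccine-event pair for a time-to-onset signal
#'
#' @inheritParams tto_scan
#' @param vaccine,event The pair of interest.
#' @return A one-row results tibble (see [tto_scan()]).
#' @export
tto_flag_pair <- function(reports, vaccine, event, alpha = 0.05,
                          window_days = 30L, min_target = 1L, exact = FALSE) {
  scan <- tto_scan(reports, alpha = alpha, window_days = window_days,
                   min_target = min_target, exact = exact,
                   pairs = tibble::tibble(vaccine = vaccine, event = event))
  scan$results
}

#' @export
print.tto_scan <- function(x, ...) {
  cat("<tto_scan> ", x$label, ": ", nrow(x$results), " pairs, ",
      sum(x$results$flagged), " flagged (",
      sum(x$results$status == "OK"), " testable)\n", sep = "")
  invisible(x)
}
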