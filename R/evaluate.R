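#' Confusion-matrix rates
#'
#' Derives positive/negative predictive value, sensitivity and specificity
#' from the four confusion cells.  A rate whose denominator is zero is `NA`.
#'
#' @param tp,fp,tn,fn Non-negative integer vectors (recycled).
#' @return A tibble with columns `tp`, `fp`, `tn`, `fn`, `ppv`, `npv`,
#'   `sensitivity`, `specificity`.
#' @export
#' @examples
#' confusion_metrics(77, 53, 8791, 722)
confusion_metrics <- function(tp, fp, tn, fn) {
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp))
}

#' Classify flagged pairs against a gold standard
#'
#' Classifies every pair of the evaluation universe (the *reported* pairs --
#' never a full vaccine x event cross product) as true/false
#' positive/negative: TP = flagged and labelled, FP = flagged and unlabelled,
#' FN = labelled but not flagged, TN = the rest.  Pairs whose vaccine is not
#' covered by the gold standard cannot be evaluated and are excluded (with a
#' warning and an `n_excluded` count), so
#' `tp + fp + tn + fn + n_excluded == nrow(universe)`.
#'
#' @param flagged Tibble of flagged pairs (`vaccine`, `event`); must be a
#'   subset of `universe`.
#' @param universe Tibble of all evaluable reported pairs.
#' @param gold A gold standard (see [read_gold_standard()]).
#' @param by `"overall"` for one row, `"vaccine"` for per-vaccine rows.
#' @return A tibble of confusion cells and rates (see [confusion_metrics()])
#'   plus `n_excluded`; one row overall or one per vaccine.
#' @export
classify_signals <- function(flagged, universe, gold,
                             by = c("overall", "vaccine")) {
  by <- match.arg(by)
  universe <- dplyr::distinct(tibble::as_tibble(universe)[c("vaccine", "event")])
  flagged <- dplyr::distinct(tibble::as_tibble(flagged)[c("vaccine", "event")])
  extra <- dplyr::anti_join(flagged, universe, by = c("vaccine", "event"))
  if (nrow(extra) > 0) {
    warning(nrow(extra), " flagged pair(s) outside the universe were ignored",
            call. = FALSE)
    flagged <- dplyr::semi_join(flagged, universe, by = c("vaccine", "event"))
  }
  truth <- gold_lookup(gold, universe$vaccine, universe$event)
  is_flagged <- paste(universe$vaccine, universe$event, sep = "\r") %in%
    paste(flagged$vaccine, flagged$event, sep = "\r")
  excluded <- is.na(truth)
  if (any(excluded)) {
    warning(sum(excluded), " pair(s) excluded: vaccine not covered by the ",
            "gold standard", call. = FALSE)
  }
  df <- tibble::tibble(vaccine = universe$vaccine, truth = truth,
                       flag = is_flagged)[!excluded, , drop = FALSE]
  cells <- function(d) {
    confusion_metrics(tp = sum(d$flag & d$truth), fp = sum(d$flag & !d$truth),
                      tn = sum(!d$flag & !d$truth), fn = sum(!d$flag & d$truth))
  }
  if (by == "overall") {
    out <- cells(df)
    out$n_excluded <- sum(excluded)
    out
  } else {
    out <- df |>
      dplyr::group_by(.data$vaccine) |>
      dplyr::group_modify(~cells(.x)) |>
      dplyr::ungroup()
    out$n_excluded <- NA_integer_
    out
  }
}

#' Rank algorithms by positive predictive value within vaccines
#'
#' Within each vaccine, algorithms are ranked by descending PPV (rank 1 =
#' highest PPV), ties receiving midranks; each algorithm is then summarised
#' by the median and standard deviation of its ranks across vaccines -- the
#' benchmark's primary performance measure.  An algorithm with undefined PPV
#' for a vaccine (it flagged nothing there) is dropped from that vaccine's
#' rank vector rather than imputed.
#'
#' @param ppv_tbl Long tibble with columns `algorithm`, `vaccine`, `ppv`
#'   (`NA` = undefined).
#' @return A tibble `algorithm`, `median_rank`, `rank_sd`, `n_vaccines`
#'   sorted by ascending median rank, with the full per-vaccine rank table in
#'   attribute `"ranks"`.
#' @export
rank_algorithms <- function(ppv_tbl) {
  stopifnot(all(c("algorithm", "vaccine", "ppv") %in% names(ppv_tbl)))
  if (dplyr::n_distinct(ppv_tbl$algorithm) < 2) {
    stop("need at least two algorithms to rank", call. = FALSE)
  }
  ranks <- ppv_tbl |>
    dplyr::filter(!is.na(.data$ppv)) |>
    dplyr::group_by(.data$vaccine) |>
    dplyr::mutate(rank = rank(-.data$ppv, ties.method = "average")) |>
    dplyr::ungroup()
  out <- ranks |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(median_rank = median(.data$rank),
                     rank_sd = sd(.data$rank),
                     n_vaccines = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$median_rank, .data$algorithm)
  attr(out, "ranks") <- ranks
  out
}

#' ROC curve over a threshold sweep
#'
#' Sweeps a flagging threshold over per-pair scores and classifies at each
#' point.  For the shrinker the score is EB05 and a pair is flagged when the
#' score strictly exceeds the threshold (`direction = "greater"`, thresholds
#' 0 to 10 by 0.1); for the time-to-onset detector the score is the larger of
#' the two KS p-values -- so "score < alpha" is exactly the both-significant
#' rule -- and flagging uses `direction = "less"` (thresholds 0 to 1 by
#' 0.01).  Pairs with `NA` scores (e.g. no testable onset data) are never
#' flagged, which caps attainable sensitivity below 1.
#'
#' @param scores Tibble with columns `vaccine`, `event`, `score` (`NA`
#'   allowed); the rows are the evaluation universe.
#' @param gold A gold standard.
#' @param thresholds Numeric vector of cut-offs to sweep.
#' @param direction `"greater"` flags `score > t`; `"less"` flags
#'   `score < t`.
#' @return A `roc_curve` tibble: `threshold`, `sensitivity`, `specificity`,
#'   `one_minus_specificity`.
#' @export
roc_curve <- function(scores, gold, thresholds,
                      direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(all(c("vaccine", "event", "score") %in% names(scores)))
  truth <- gold_lookup(gold, scores$vaccine, scores$event)
  keep <- !is.na(truth)
  s <- scores$score[keep]
  truth <- truth[keep]
  pts <- lapply(thresholds, function(t) {
    flag <- if (direction == "greater") !is.na(s) & s > t else !is.na(s) & s < t
    confusion_metrics(tp = sum(flag & truth), fp = sum(flag & !truth),
                      tn = sum(!flag & !truth), fn = sum(!flag & truth))
  })
  m <- dplyr::bind_rows(pts)
  out <- tibble::tibble(threshold = thresholds,
                        sensitivity = m$sensitivity,
                        specificity = m$specificity,
                        one_minus_specificity = 1 - m$specificity)
  class(out) <- c("roc_curve", class(out))
  out
}

#' Benchmark a set of algorithms Table-3 style
#'
#' Combines overall confusion metrics with the per-vaccine PPV median-rank
#' protocol for any number of algorithm runs, producing one row per
#' algorithm sorted by ascending median rank.
#'
#' @param flags Long tibble of flagged pairs: `algorithm`, `vaccine`,
#'   `event`.  Algorithms that flagged nothing anywhere still appear if
#'   listed in `algorithms`.
#' @param universe Tibble of evaluable reported pairs (`vaccine`, `event`).
#' @param gold A gold standard.
#' @param algorithms Optional character vector fixing the algorithm set and
#'   order of interest (default: those present in `flags`).
#' @return A tibble with columns `algorithm`, `median_rank`, `rank_sd`,
#'   `ppv`, `npv`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`.
#' @export
benchmark_algorithms <- function(flags, universe, gold, algorithms = NULL) {
  if (is.null(algorithms)) algorithms <- unique(flags$algorithm)
  universe <- dplyr::distinct(tibble::as_tibble(universe)[c("vaccine", "event")])
  covered <- universe$vaccine %in% unique(gold$vaccine)
  if (any(!covered)) {
    message(sum(!covered), " pair(s) excluded from the benchmark: vaccine ",
            "not covered by the gold standard")
    universe <- universe[covered, , drop = FALSE]
    flags <- flags[flags$vaccine %in% unique(gold$vaccine), , drop = FALSE]
  }
  per_alg <- lapply(algorithms, function(a) {
    fl <- flags[flags$algorithm == a, c("vaccine", "event")]
    overall <- classify_signals(fl, universe, gold, by = "overall")
    by_vac <- classify_signals(fl, universe, gold, by = "vaccine")
    list(overall = dplyr::mutate(overall, algorithm = a, .before = 1),
         ppv = tibble::tibble(algorithm = a, vaccine = by_vac$vaccine,
                              ppv = by_vac$ppv))
  })
  overall <- dplyr::bind_rows(lapply(per_alg, `[[`, "overall"))
  ranks <- rank_algorithms(dplyr::bind_rows(lapply(per_alg, `[[`, "ppv")))
  out <- ranks |>
    dplyr::left_join(overall, by = "algorithm") |>
    dplyr::select("algorithm", "median_rank", "rank_sd", "ppv", "npv",
                  "tp", "fp", "tn", "fn", "sensitivity", "specificity")
  out
}
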