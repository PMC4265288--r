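#' Mantel-Haenszel stratified expected counts
#'
#' Under independence of vaccine and event within each stratum, the expected
#' report count for a pair is
#' \deqn{E(v,e) = \sum_s \frac{n_{v\cdot s}\, n_{\cdot e s}}{n_{\cdot\cdot s}}}
#' summed over strata where the grand total is positive.  Only pairs observed
#' at least once are returned (the reported-pair universe); the sum runs over
#' *all* strata where both the vaccine and the event occur, not only strata
#' where they co-occur.
#'
#' @param counts A [build_pair_counts()] result.
#' @return A tibble with one row per reported pair: `vaccine`, `event`,
#'   `n` (observed count summed over strata) and `expected`.
#' @export
expected_counts <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  pairs <- dplyr::count(counts$cells, .data$vaccine, .data$event,
                        wt = .data$n, name = "n")
  ev <- dplyr::inner_join(counts$event_margin, counts$stratum_margin,
                          by = "stratum")
  expected <- pairs |>
    dplyr::select("vaccine", "event") |>
    dplyr::inner_join(counts$vaccine_margin, by = "vaccine",
                      relationship = "many-to-many") |>
    dplyr::inner_join(ev, by = c("event", "stratum")) |>
    dplyr::group_by(.data$vaccine, .data$event) |>
    dplyr::summarise(
      expected = sum(.data$n_vaccine * .data$n_event / .data$n_total),
      .groups = "drop")
  dplyr::inner_join(pairs, expected, by = c("vaccine", "event"))
}

## -------------------------------------------------------------------------
## Gamma-mixture empirical Bayes prior
## -------------------------------------------------------------------------

## Marginal log-density of N given E under one gamma component: a
## gamma-Poisson mixture is negative binomial with size = shape and
## prob = rate / (rate + E).
nb_logdens <- function(n, e, shape, rate) {
  stats::dnbinom(n, size = shape, prob = rate / (rate + e), log = TRUE)
}

## log P(component 1 | N, E) and mixture marginal log-likelihood terms
gps_loglik_terms <- function(n, e, prior) {
  l1 <- log(prior$P) + nb_logdens(n, e, prior$alpha1, prior$beta1)
  l2 <- log1p(-prior$P) + nb_logdens(n, e, prior$alpha2, prior$beta2)
  m <- pmax(l1, l2)
  list(l1 = l1, l2 = l2, ll = m + log(exp(l1 - m) + exp(l2 - m)))
}

new_gps_prior <- function(alpha1, beta1, alpha2, beta2, P,
                          loglik = NA_real_, converged = NA, n_pairs = NA_integer_) {
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, P = P, loglik = loglik,
                 converged = converged, n_pairs = n_pairs),
            class = "gps_prior")
}

#' Construct a gamma-mixture shrinkage prior
#'
#' The empirical-Bayes model places on the relative reporting ratio
#' \eqn{\lambda = \mu/E} a two-component gamma mixture prior
#' \eqn{P\,\Gamma(\alpha_1,\beta_1) + (1-P)\,\Gamma(\alpha_2,\beta_2)}
#' (shape/rate parameterisation).  Normally obtained from [fit_gps_prior()];
#' this constructor builds one directly, e.g. for simulation.
#'
#' @param alpha1,beta1,alpha2,beta2 Positive shape/rate parameters.
#' @param P Mixture weight of the first component, in `[0, 1]`.
#' @return An object of class `gps_prior`.
#' @export
gps_prior <- function(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, P = 1/3) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, P >= 0, P <= 1)
  new_gps_prior(alpha1, beta1, alpha2, beta2, P)
}

#' @export
print.gps_prior <- function(x, ...) {
  cat(sprintf(
    "<gps_prior> a1=%.4g b1=%.4g a2=%.4g b2=%.4g P=%.4g", x$alpha1, x$beta1,
    x$alpha2, x$beta2, x$P))
  if (!is.na(x$loglik)) {
    cat(sprintf("  (loglik %.2f on %d pairs%s)", x$loglik, x$n_pairs,
                if (isTRUE(x$converged)) "" else ", NOT converged"))
  }
  cat("\n")
  invisible(x)
}

#' Fit the shrinkage prior by maximum marginal likelihood
#'
#' Maximises the marginal likelihood of the observed counts, which under the
#' gamma-Poisson model is a two-component negative binomial mixture:
#' \deqn{\prod_i \left[ P\,\mathrm{NB}(N_i;\alpha_1,\tfrac{\beta_1}{\beta_1+E_i})
#'   + (1-P)\,\mathrm{NB}(N_i;\alpha_2,\tfrac{\beta_2}{\beta_2+E_i}) \right].}
#' Optimisation is on log-transformed shapes/rates and logit-transformed `P`
#' (Nelder-Mead followed by a BFGS polish), declaring convergence when the
#' log-likelihood improves by less than `tol`.
#'
#' @param n Integer vector of observed pair counts (all `>= 1` by convention:
#'   unobserved pairs are not enumerated).
#' @param e Positive vector of expected counts, same length.
#' @param start Starting prior (default: the conventional starting values
#'   `gps_prior(0.2, 0.1, 2, 4, 1/3)`).
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Iteration cap for each optimiser stage.
#' @return A `gps_prior` with `loglik`, `converged` and `n_pairs` filled in.
#'   Non-convergence raises an error of class `vaxsignal_nonconvergence`
#'   carrying the best-so-far prior in its `prior` field.
#' @export
fit_gps_prior <- function(n, e, start = gps_prior(), tol = 1e-8,
                          max_iter = 2000L) {
  stopifnot(length(n) == length(e), length(n) >= 2)
  if (any(e <= 0)) stop("all expected counts must be positive", call. = FALSE)
  n <- as.numeric(n)

  nll <- function(theta) {
    pr <- list(alpha1 = exp(theta[1]), beta1 = exp(theta[2]),
               alpha2 = exp(theta[3]), beta2 = exp(theta[4]),
               P = stats::plogis(theta[5]))
    v <- -sum(gps_loglik_terms(n, e, pr)$ll)
    if (!is.finite(v)) 1e300 else v
  }
  theta0 <- c(log(start$alpha1), log(start$beta1), log(start$alpha2),
              log(start$beta2), stats::qlogis(min(max(start$P, 1e-8), 1 - 1e-8)))

  o1 <- optim(theta0, nll, method = "Nelder-Mead",
              control = list(maxit = max_iter, reltol = tol))
  o2 <- tryCatch(
    optim(o1$par, nll, method = "BFGS",
          control = list(maxit = max_iter, reltol = tol)),
    error = function(err) o1)
  best <- if (o2$value <= o1$value) o2 else o1
  th <- best$par
  prior <- new_gps_prior(exp(th[1]), exp(th[2]), exp(th[3]), exp(th[4]),
                         stats::plogis(th[5]),
                         loglik = -best$value,
                         converged = best$convergence == 0,
                         n_pairs = length(n))
  if (!prior$converged) {
    cond <- structure(
      class = c("vaxsignal_nonconvergence", "error", "condition"),
      list(message = sprintf(
             "prior fit did not converge within %d iterations (loglik %.4f)",
             max_iter, prior$loglik),
           call = sys.call(-1), prior = prior))
    stop(cond)
  }
  prior
}

#' Posterior shrinkage summaries for observed pairs
#'
#' Given `N` observed and `E` expected reports, the posterior of the relative
#' reporting ratio \eqn{\lambda} is the gamma mixture
#' \eqn{Q\,\Gamma(\alpha_1+N,\beta_1+E) + (1-Q)\,\Gamma(\alpha_2+N,\beta_2+E)},
#' with `Q` the posterior weight of the first component.  The empirical Bayes
#' geometric mean is \eqn{EBGM = \exp(E[\ln\lambda])} (via the digamma
#' function) and EB05/EB95 are the 5th/95th posterior percentiles -- the
#' bounds of the two-sided 90% credibility interval -- found by root-finding
#' on the mixture CDF.
#'
#' @param n Vector of observed counts (`>= 0`).
#' @param e Vector of positive expected counts.
#' @param prior A `gps_prior`.
#' @return A tibble with columns `n`, `e`, `q`, `ebgm`, `eb05`, `eb95`.
#' @export
#' @examples
#' gps_posterior(10, 2, gps_prior())
gps_posterior <- function(n, e, prior) {
  stopifnot(inherits(prior, "gps_prior"))
  if (any(e <= 0)) stop("expected counts must be positive", call. = FALSE)
  k <- max(length(n), length(e))
  n <- rep_len(as.numeric(n), k)
  e <- rep_len(as.numeric(e), k)

  terms <- gps_loglik_terms(n, e, prior)
  q <- 1 / (1 + exp(terms$l2 - terms$l1))
  q[prior$P == 1] <- 1
  q[prior$P == 0] <- 0

  a1 <- prior$alpha1 + n; b1 <- prior$beta1 + e
  a2 <- prior$alpha2 + n; b2 <- prior$beta2 + e
  ebgm <- exp(q * (digamma(a1) - log(b1)) + (1 - q) * (digamma(a2) - log(b2)))

  eb05 <- mixture_gamma_quantile(0.05, q, a1, b1, a2, b2)
  eb95 <- mixture_gamma_quantile(0.95, q, a1, b1, a2, b2)
  tibble::tibble(n = n, e = e, q = q, ebgm = ebgm, eb05 = eb05, eb95 = eb95)
}

## Quantile of q*Gamma(a1,b1) + (1-q)*Gamma(a2,b2) by root-finding on the
## CDF.  The component p-quantiles bracket the mixture quantile.
mixture_gamma_quantile <- function(p, q, a1, b1, a2, b2) {
  k <- length(q)
  out <- numeric(k)
  q1 <- qgamma(p, a1, rate = b1)
  q2 <- qgamma(p, a2, rate = b2)
  lo <- pmin(q1, q2)
  hi <- pmax(q1, q2)
  for (i in seq_len(k)) {
    if (hi[i] - lo[i] < 1e-12 * max(hi[i], 1e-300)) { out[i] <- q1[i]; next }
    f <- function(x) {
      q[i] * pgamma(x, a1[i], rate = b1[i]) +
        (1 - q[i]) * pgamma(x, a2[i], rate = b2[i]) - p
    }
    # the component quantiles bracket the root in exact arithmetic; pad
    # against rounding at the endpoints
    l <- lo[i] * (1 - 1e-9); h <- hi[i] * (1 + 1e-9)
    it <- 0
    while (f(l) > 0 && it < 60) { l <- l / 2; it <- it + 1 }
    while (f(h) < 0 && it < 120) { h <- h * 2; it <- it + 1 }
    out[i] <- uniroot(f, lower = l, upper = h,
                      tol = 1e-11 * max(1, h))$root
  }
  out
}

## -------------------------------------------------------------------------
## The detector
## -------------------------------------------------------------------------

#' Run the gamma Poisson shrinker on a report database
#'
#' Builds stratified pair counts, computes Mantel-Haenszel expected counts,
#' fits the shrinkage prior on all reported pairs of the database (the
#' background is the whole database, all vaccines), and produces posterior
#' EBGM / EB05 / EB95 summaries per pair.  If `threshold` is given, pairs
#' with `EB05 > threshold` (strict) are flagged.
#'
#' @param reports A reports tibble.
#' @param stratification A stratification label (see [all_stratifications()])
#'   or a [stratum_spec()].
#' @param threshold EB05 cut-off, or `NULL` for scores only.
#' @param age_bins Age breakpoints passed to [stratum_spec()] when
#'   `stratification` is a label.
#' @param prior Optionally, a prefit `gps_prior` to reuse (e.g. to share one
#'   prior across stratifications); default refits on this database.
#' @return An object of class `mgps_fit`: list with `results` (tibble
#'   `vaccine`, `event`, `n`, `expected`, `q`, `ebgm`, `eb05`, `eb95`, and
#'   `flagged` when a threshold is set), `prior`, `spec`, `threshold`,
#'   `label`.
#' @seealso [mgps_flag()], [mgps_grid()], [tidy.mgps_fit()]
#' @export
run_mgps <- function(reports, stratification = "SARY", threshold = NULL,
                     age_bins = c(0, 2, 12, 18, 46, 66, Inf), prior = NULL) {
  spec <- if (inherits(stratification, "stratum_spec")) stratification
          else stratum_spec(stratification, age_bins)
  counts <- build_pair_counts(reports, spec)
  pairs <- expected_counts(counts)
  if (is.null(prior)) prior <- fit_gps_prior(pairs$n, pairs$expected)
  post <- gps_posterior(pairs$n, pairs$expected, prior)
  results <- dplyr::bind_cols(
    pairs[c("vaccine", "event", "n", "expected")],
    post[c("q", "ebgm", "eb05", "eb95")])
  fit <- structure(list(results = results, prior = prior, spec = spec,
                        threshold = threshold, label = NULL),
                   class = "mgps_fit")
  if (!is.null(threshold)) fit <- mgps_flag(fit, threshold)
  fit
}

#' Apply an EB05 flagging threshold to a fitted shrinker
#'
#' Flags pairs whose EB05 strictly exceeds the cut-off.  Re-thresholding does
#' not refit anything, so sweeping thresholds over one fit is cheap.
#'
#' @param fit An `mgps_fit`.
#' @param threshold EB05 cut-off (the grid uses 0 to 4 by 0.2).
#' @return The `mgps_fit` with a `flagged` column and its grid `label`
#'   (e.g. `"0.8-SARY"`) set.
#' @export
mgps_flag <- function(fit, threshold) {
  stopifnot(inherits(fit, "mgps_fit"))
  fit$results$flagged <- fit$results$eb05 > threshold
  fit$threshold <- threshold
  fit$label <- paste0(format_threshold(threshold), "-", fit$spec$label)
  fit
}

#' @export
print.mgps_fit <- function(x, ...) {
  cat("<mgps_fit> ",
      if (!is.null(x$label)) x$label else x$spec$label, ": ",
      nrow(x$results), " pairs", sep = "")
  if (!is.null(x$threshold)) cat(", ", sum(x$results$flagged), " flagged")
  cat("\n")
  print(x$prior)
  invisible(x)
}

## "0.8", "2", "2.4": minimal digits, trailing zeros trimmed
format_threshold <- function(x) {
  vapply(x, function(t) format(round(t, 2), trim = TRUE, drop0trailing = TRUE),
         character(1))
}

#' The 336-configuration disproportionality grid
#'
#' Crosses the 16 stratification-factor subsets with 21 EB05 cut-offs (0 to 4
#' by 0.2).  Each configuration is labelled `"threshold-stratification"`
#' with minimal digits, e.g. `"0.8-SARY"`, `"2-U"`.
#'
#' @return A tibble with columns `label`, `threshold`, `stratification`
#'   (336 rows, unique labels).
#' @export
mgps_grid <- function() {
  g <- tidyr::expand_grid(stratification = all_stratifications(),
                          threshold = round(seq(0, 4, by = 0.2), 1))
  tibble::tibble(
    label = paste0(format_threshold(g$threshold), "-", g$stratification),
    threshold = g$threshold,
    stratification = g$stratification)
}
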