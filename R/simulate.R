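#' Configure a synthetic spontaneous-report database
#'
#' Describes a multi-vaccine, multi-event stream of spontaneous reports with
#' the statistical structure both detectors assume: skewed vaccine and event
#' reporting propensities, stratum-dependent reporting rates, per-vaccine
#' time-to-onset missingness, a reporting-bias decay in the background
#' onset-delay distribution (events occurring long after immunisation are
#' less likely to be reported), and injected true signals of several kinds:
#'
#' * `"background"` profile with `rel_rate > 1`: a pure disproportionality
#'   signal (excess reporting, unremarkable onset delays);
#' * `"clustered"`: onset delays concentrated near `mode_days` (discretised
#'   log-normal), detectable from their temporal pattern;
#' * `"long"`: onset delays uniform on 91--365 days, outside every screening
#'   window (a time-to-onset blind spot);
#' * `"missing"`: onset delay always missing (the other blind spot).
#'
#' Signals can be given explicitly via `signals` or injected automatically
#' by count; automatic picks choose cells whose baseline expected count lies
#' in `dpa_mu_range` / `tto_mu_range` so injected pairs are neither trivial
#' nor hopeless at the configured database size.
#'
#' @param n_vaccines,n_events,n_reports Database dimensions; `n_reports` is
#'   the expected total number of report rows.
#' @param vaccine_prop,event_prop Optional marginal reporting propensities
#'   (normalised internally); default drawn once from skewed gamma variates.
#' @param signals Optional tibble with columns `vaccine`, `event`,
#'   `rel_rate`, `tto_profile`, `mode_days` overriding automatic injection.
#' @param n_dpa_signals,dpa_rel_rate Number and relative reporting rate of
#'   injected disproportionality signals.
#' @param n_tto_signals,tto_mode_days Number of injected clustered-onset
#'   signals and the mode (days) of their delay distribution.
#' @param n_long_blind,n_missing_blind Numbers of injected
#'   disproportionality-strength signals with long or missing onset delays.
#' @param dpa_mu_range,tto_mu_range Baseline expected-count bands for
#'   automatic signal placement.
#' @param tto_missingness Per-vaccine probability that a report's onset
#'   delay is missing; default drawn uniformly from `[0.12, 0.52]`.
#' @param bg_tto_mean Mean (days) of the geometric background onset-delay
#'   distribution, truncated at `tto_max`.
#' @param tto_max Truncation (days) for all onset delays.
#' @param strata_effects Multiplicative reporting-rate modifiers:
#'   list with named vectors `sex`, `region` and scalar `year_drift`
#'   (per-year multiplicative trend).
#' @param vaccine_profiles Optional tibble of per-vaccine demographics:
#'   `vaccine`, `age_meanlog`, `age_sdlog`, `female_frac`, `missing`,
#'   `year_lo`, `year_hi`, `share` (relative report volume).
#' @param date_range Character vector of length 2, ISO dates bounding
#'   receipt dates.
#' @param seed Integer; fully determines the generated database.
#' @return An object of class `sim_config`.
#' @seealso [simulate_database()], [table_like_fixture()]
#' @export
sim_config <- function(n_vaccines = 20, n_events = 250, n_reports = 50000,
                       vaccine_prop = NULL, event_prop = NULL,
                       signals = NULL,
                       n_dpa_signals = 0, dpa_rel_rate = 10,
                       n_tto_signals = 0, tto_mode_days = 2,
                       n_long_blind = 0, n_missing_blind = 0,
                       dpa_mu_range = c(5, 40), tto_mu_range = c(50, 400),
                       tto_missingness = NULL, bg_tto_mean = 10,
                       tto_max = 365,
                       strata_effects = list(
                         sex = c(F = 1.1, M = 0.9),
                         region = c(EU = 1.2, NAM = 1.0, AS = 0.9, SAM = 0.8,
                                    AF = 0.7, OC = 1.0),
                         year_drift = 1.03),
                       vaccine_profiles = NULL,
                       date_range = c("2000-01-01", "2010-02-01"),
                       seed = 1L) {
  stopifnot(n_vaccines >= 2, n_events >= 2, n_reports > 0,
            bg_tto_mean > 0, tto_max > 0)
  if (!is.null(tto_missingness)) {
    stopifnot(all(tto_missingness >= 0 & tto_missingness <= 1))
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_vaccines, " vaccines x ", x$n_events,
      " events, ~", x$n_reports, " reports, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

## Draw from a geometric distribution truncated at max_days (inverse CDF),
## emulating the reporting-bias decay of onset delays.
rtrunc_geom <- function(n, mean_days, max_days) {
  p <- 1 / (1 + mean_days)
  stats::qgeom(runif(n) * stats::pgeom(max_days, p), p)
}

## Discretised log-normal with mode at mode_days (sdlog 0.5), clamped.
rcluster_tto <- function(n, mode_days, max_days) {
  s <- 0.5
  x <- round(rlnorm(n, meanlog = log(mode_days) + s^2, sdlog = s))
  pmin(pmax(x, 0), max_days)
}

## tilt a probability vector by multiplicative rate effects
tilt <- function(p, effect) { q <- p * effect; q / sum(q) }

#' Simulate a spontaneous-report database
#'
#' Draws pair counts as Poisson with mean `baseline x relative rate`, then
#' attaches per-report demographics from the vaccine's profile (tilted by the
#' stratum rate effects), receipt dates, and onset delays per the pair's
#' time-to-onset profile (see [sim_config()]).  The injected-signal list
#' doubles as the ground-truth gold standard, so simulation output feeds the
#' evaluation module unchanged.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_db`: list with `reports` (a reports
#'   tibble sorted by receipt date), `truth` (tibble `vaccine`, `event`,
#'   `rel_rate`, `tto_profile`, `mode_days`), `gold` (the truth as a
#'   `gold_standard`), and `config`.
#' @export
#' @examples
#' db <- simulate_database(sim_config(n_vaccines = 4, n_events = 20,
#'                                    n_reports = 500, seed = 7))
#' db$reports
simulate_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nv <- config$n_vaccines; ne <- config$n_events
  vaccines <- sprintf("V%02d", seq_len(nv))
  events <- sprintf("E%03d", seq_len(ne))

  vp <- config$vaccine_prop
  if (is.null(vp) && !is.null(config$vaccine_profiles)) {
    vp <- config$vaccine_profiles$share
  }
  if (is.null(vp)) vp <- rgamma(nv, shape = 1)
  vp <- vp / sum(vp)
  ep <- config$event_prop
  if (is.null(ep)) ep <- rgamma(ne, shape = 0.7)
  ep <- ep / sum(ep)

  prof <- config$vaccine_profiles
  if (is.null(prof)) {
    # cycle through infant / child / adolescent / adult / elderly archetypes
    arche <- tibble::tibble(
      age_meanlog = log(c(0.5, 5, 15, 30, 60)),
      age_sdlog = c(0.6, 0.5, 0.15, 0.5, 0.3))
    idx <- rep_len(seq_len(5), nv)
    yrs <- as.integer(format(as.Date(config$date_range), "%Y"))
    prof <- tibble::tibble(
      vaccine = vaccines,
      age_meanlog = arche$age_meanlog[idx],
      age_sdlog = arche$age_sdlog[idx],
      female_frac = runif(nv, 0.4, 0.7),
      missing = if (is.null(config$tto_missingness))
        runif(nv, 0.12, 0.52) else rep_len(config$tto_missingness, nv),
      year_lo = rep(yrs[1], nv), year_hi = rep(yrs[2], nv))
  } else {
    prof$vaccine <- vaccines
    if (!is.null(config$tto_missingness)) {
      prof$missing <- rep_len(config$tto_missingness, nv)
    }
  }

  mu <- config$n_reports * outer(vp, ep)  # baseline expected pair counts
  dimnames(mu) <- list(vaccines, events)

  signals <- config$signals
  if (is.null(signals)) {
    signals <- tibble::tibble(vaccine = character(), event = character(),
                              rel_rate = numeric(), tto_profile = character(),
                              mode_days = numeric())
    pick <- function(range, n_pick) {
      cand <- which(mu >= range[1] & mu <= range[2], arr.ind = TRUE)
      taken <- paste(signals$vaccine, signals$event)
      cand <- cand[!(paste(vaccines[cand[, 1]], events[cand[, 2]]) %in% taken),
                   , drop = FALSE]
      if (nrow(cand) < n_pick) {
        stop("not enough candidate cells in expected-count band [",
             range[1], ", ", range[2], "] to inject ", n_pick, " signal(s)",
             call. = FALSE)
      }
      sel <- cand[sample.int(nrow(cand), n_pick), , drop = FALSE]
      tibble::tibble(vaccine = vaccines[sel[, 1]], event = events[sel[, 2]])
    }
    if (config$n_dpa_signals > 0) {
      s <- pick(config$dpa_mu_range, config$n_dpa_signals)
      signals <- dplyr::bind_rows(signals, dplyr::mutate(
        s, rel_rate = config$dpa_rel_rate, tto_profile = "background",
        mode_days = NA_real_))
    }
    if (config$n_tto_signals > 0) {
      s <- pick(config$tto_mu_range, config$n_tto_signals)
      signals <- dplyr::bind_rows(signals, dplyr::mutate(
        s, rel_rate = 1, tto_profile = "clustered",
        mode_days = config$tto_mode_days))
    }
    if (config$n_long_blind > 0) {
      s <- pick(config$dpa_mu_range, config$n_long_blind)
      signals <- dplyr::bind_rows(signals, dplyr::mutate(
        s, rel_rate = config$dpa_rel_rate, tto_profile = "long",
        mode_days = NA_real_))
    }
    if (config$n_missing_blind > 0) {
      s <- pick(config$dpa_mu_range, config$n_missing_blind)
      signals <- dplyr::bind_rows(signals, dplyr::mutate(
        s, rel_rate = config$dpa_rel_rate, tto_profile = "missing",
        mode_days = NA_real_))
    }
  } else {
    signals <- tibble::as_tibble(signals)
    if (is.null(signals$tto_profile)) signals$tto_profile <- "background"
    if (is.null(signals$rel_rate)) signals$rel_rate <- 1
    if (is.null(signals$mode_days)) signals$mode_days <- NA_real_
    stopifnot(all(signals$vaccine %in% vaccines),
              all(signals$event %in% events), all(signals$rel_rate >= 1))
  }

  rate <- mu
  for (i in seq_len(nrow(signals))) {
    rate[signals$vaccine[i], signals$event[i]] <-
      mu[signals$vaccine[i], signals$event[i]] * signals$rel_rate[i]
  }
  counts <- matrix(rpois(length(rate), rate), nrow = nv,
                   dimnames = dimnames(rate))

  vi <- rep(rep(seq_len(nv), ne), times = as.vector(counts))
  ei <- rep(rep(seq_len(ne), each = nv), times = as.vector(counts))
  n <- length(vi)

  regions <- names(config$strata_effects$region)
  region_base <- matrix(rgamma(nv * length(regions), 1), nrow = nv)
  region_base <- region_base / rowSums(region_base)

  sex <- region <- rep(NA_character_, n)
  age <- numeric(n)
  year <- integer(n); day <- integer(n)
  eff <- config$strata_effects
  for (v in seq_len(nv)) {
    rows <- which(vi == v)
    if (length(rows) == 0) next
    m <- length(rows)
    pf <- tilt(c(F = prof$female_frac[v], M = 1 - prof$female_frac[v]),
               eff$sex[c("F", "M")])
    sex[rows] <- sample(c("F", "M"), m, replace = TRUE, prob = pf)
    age[rows] <- pmin(rlnorm(m, prof$age_meanlog[v], prof$age_sdlog[v]), 99)
    region[rows] <- sample(regions, m, replace = TRUE,
                           prob = tilt(region_base[v, ], eff$region))
    yrs <- prof$year_lo[v]:prof$year_hi[v]
    wy <- eff$year_drift^(yrs - yrs[1])
    year[rows] <- yrs[sample.int(length(yrs), m, replace = TRUE,
                                 prob = wy / sum(wy))]
    day[rows] <- sample.int(365, m, replace = TRUE)
  }
  # a small fraction of reports lack demographics entirely
  sex[runif(n) < 0.04] <- NA
  age[runif(n) < 0.05] <- NA
  region[runif(n) < 0.03] <- NA

  tto <- rtrunc_geom(n, config$bg_tto_mean, config$tto_max)
  key <- paste(vi, ei)
  for (i in seq_len(nrow(signals))) {
    rows <- which(key == paste(match(signals$vaccine[i], vaccines),
                               match(signals$event[i], events)))
    if (length(rows) == 0) next
    tto[rows] <- switch(signals$tto_profile[i],
      background = tto[rows],
      clustered = rcluster_tto(length(rows), signals$mode_days[i],
                               config$tto_max),
      long = sample(91:config$tto_max, length(rows), replace = TRUE),
      missing = NA_integer_)
  }
  drop_tto <- runif(n) < prof$missing[vi]
  tto[drop_tto] <- NA_integer_

  date <- as.Date(sprintf("%d-01-01", year)) + (day - 1L)
  lo <- as.Date(config$date_range[1]); hi <- as.Date(config$date_range[2])
  date <- pmin(pmax(date, lo), hi)

  reports <- tibble::tibble(
    report_id = sprintf("R%07d", seq_len(n)),
    receipt_date = date,
    vaccine = vaccines[vi],
    event = events[ei],
    sex = sex,
    age_years = round(age, 1),
    region = region,
    report_year = as.integer(format(date, "%Y")),
    tto_days = as.integer(tto))
  reports <- reports[order(reports$receipt_date, reports$report_id), ,
                     drop = FALSE]

  structure(list(reports = reports, truth = signals,
                 gold = if (nrow(signals) > 0) as_gold_standard(signals)
                        else NULL,
                 config = config),
            class = "sim_db")
}

#' @export
print.sim_db <- function(x, ...) {
  cat("<sim_db> ", nrow(x$reports), " reports, ",
      dplyr::n_distinct(paste(x$reports$vaccine, x$reports$event)),
      " pairs, ", nrow(x$truth), " injected signal(s)\n", sep = "")
  invisible(x)
}

#' A deterministic eight-vaccine reference fixture
#'
#' Generates a small (~2,000 report) database of eight vaccines spanning
#' infant, paediatric, adolescent and adult target populations, with
#' heterogeneous report volumes, female fractions, reporting-year windows and
#' per-vaccine onset-delay missingness between 12% and 52% -- the standard
#' test fixture.  A handful of disproportionality and clustered-onset
#' signals (plus one long-delay and one missing-delay blind-spot signal) are
#' injected so every detector has something to find.  Regeneration with the
#' same seed is byte-identical.
#'
#' @param seed Integer seed.
#' @return A `sim_db` (see [simulate_database()]).
#' @export
table_like_fixture <- function(seed = 42L) {
  profiles <- tibble::tibble(
    vaccine = sprintf("V%02d", 1:8),
    age_meanlog = log(c(31, 23, 15, 5, 1.5, 0.3, 41, 31)),
    age_sdlog = c(0.55, 0.6, 0.12, 0.8, 0.4, 0.5, 0.5, 0.5),
    female_frac = c(0.64, 0.58, 0.99, 0.46, 0.43, 0.46, 0.60, 0.58),
    missing = c(0.519, 0.394, 0.220, 0.179, 0.122, 0.153, 0.325, 0.330),
    year_lo = c(1993, 1998, 2007, 2003, 1999, 2006, 2002, 2003),
    year_hi = c(2008, 2008, 2009, 2008, 2004, 2009, 2008, 2009),
    share = c(0.234, 0.062, 0.023, 0.066, 0.007, 0.019, 0.047, 0.067))
  cfg <- sim_config(
    n_vaccines = 8, n_events = 60, n_reports = 2000,
    vaccine_profiles = profiles,
    n_dpa_signals = 3, n_tto_signals = 3,
    n_long_blind = 1, n_missing_blind = 1,
    dpa_mu_range = c(3, 15), tto_mu_range = c(15, 120),
    date_range = c("1993-01-01", "2010-02-01"),
    seed = seed)
  simulate_database(cfg)
}
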