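test_that("confusion rates follow their defining formulas", {
  m <- confusion_metrics(10, 10, 70, 10)
  expect_equal(m$ppv, 0.5)
  expect_equal(m$npv, 70 / 80)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 70 / 80)
  # zero denominators give NA, not NaN or error
  m0 <- confusion_metrics(0, 0, 5, 5)
  expect_true(is.na(m0$ppv))
})

test_that("classification conserves the universe and excludes uncovered vaccines", {
  universe <- tidyr::expand_grid(vaccine = c("V1", "V2", "V3"),
                                 event = c("E1", "E2"))
  gold <- as_gold_standard(tibble::tibble(vaccine = c("V1", "V2"),
                                          event = c("E1", "E1")))
  flagged <- tibble::tibble(vaccine = c("V1", "V2"), event = c("E1", "E2"))
  expect_warning(m <- classify_signals(flagged, universe, gold),
                 "not covered")
  expect_equal(m$tp, 1)   # V1-E1 flagged and labelled
  expect_equal(m$fp, 1)   # V2-E2 flagged, unlabelled
  expect_equal(m$fn, 1)   # V2-E1 labelled, unflagged
  expect_equal(m$tn, 1)   # V1-E2
  expect_equal(m$n_excluded, 2)  # V3 pairs are not evaluable
  expect_equal(m$tp + m$fp + m$tn + m$fn + m$n_excluded, nrow(universe))
  # degenerate: flag everything -> sensitivity 1, specificity 0
  g2 <- as_gold_standard(tibble::tibble(vaccine = "V1", event = "E1"))
  u2 <- universe[universe$vaccine == "V1", ]
  m2 <- classify_signals(u2, u2, g2)
  expect_equal(m2$fn, 0); expect_equal(m2$tn, 0)
  expect_equal(m2$sensitivity, 1); expect_equal(m2$specificity, 0)
})

test_that("PPV ranking uses descending midranks and median aggregation", {
  ppv <- tidyr::expand_grid(vaccine = c("A", "B", "C"),
                            algorithm = c("a1", "a2"))
  ppv$ppv <- ifelse(ppv$algorithm == "a1", 0.6, 0.2)
  rk <- rank_algorithms(ppv)
  expect_equal(rk$algorithm, c("a1", "a2"))
  expect_equal(rk$median_rank, c(1, 2))
  # ties get midranks
  tie <- tibble::tibble(algorithm = c("a1", "a2"), vaccine = "A",
                        ppv = c(0.4, 0.4))
  rk2 <- rank_algorithms(tie)
  expect_equal(rk2$median_rank, c(1.5, 1.5))
})

test_that("median ranks equal a brute-force sort-and-rank oracle", {
  set.seed(17)
  algs <- paste0("alg", 1:5)
  vaccs <- paste0("V", 1:4)
  ppv <- tidyr::expand_grid(algorithm = algs, vaccine = vaccs)
  ppv$ppv <- round(runif(nrow(ppv)), 2)   # rounding forces some ties
  rk <- rank_algorithms(ppv)
  # oracle: independent base-R ranking per vaccine
  mat <- matrix(ppv$ppv[order(ppv$vaccine, ppv$algorithm)],
                nrow = length(algs), dimnames = list(sort(algs), NULL))
  oracle_ranks <- apply(mat, 2, function(col) rank(-col))
  expect_equal(setNames(rk$median_rank, rk$algorithm)[sort(algs)],
               apply(oracle_ranks, 1, median))
  # midranks sum to n(n+1)/2 within each vaccine
  expect_true(all(colSums(oracle_ranks) == length(algs) * (length(algs) + 1) / 2))
  r_tbl <- attr(rk, "ranks")
  sums <- tapply(r_tbl$rank, r_tbl$vaccine, sum)
  expect_true(all(sums == length(algs) * (length(algs) + 1) / 2))
  # rank 1 is the maximum PPV within each vaccine
  best <- tapply(seq_len(nrow(r_tbl)), r_tbl$vaccine,
                 function(i) r_tbl$ppv[i][which.min(r_tbl$rank[i])])
  top <- tapply(r_tbl$ppv, r_tbl$vaccine, max)
  expect_equal(as.numeric(best), as.numeric(top))
})

test_that("undefined PPVs are dropped from the rank vector, not imputed", {
  ppv <- tibble::tibble(
    algorithm = rep(c("a1", "a2"), each = 2),
    vaccine = rep(c("A", "B"), 2),
    ppv = c(0.5, NA, 0.3, 0.9))
  rk <- rank_algorithms(ppv)
  expect_equal(rk$n_vaccines[rk$algorithm == "a1"], 1)
  expect_equal(rk$median_rank[rk$algorithm == "a1"], 1)  # only vaccine A
})

test_that("ROC sweeps match brute-force per-threshold classification", {
  set.seed(23)
  uni <- tidyr::expand_grid(vaccine = paste0("V", 1:4),
                            event = paste0("E", 1:25))
  gold <- as_gold_standard(uni[sample.int(100, 20), ])
  scores <- dplyr::mutate(uni, score = ifelse(runif(100) < 0.1, NA,
                                              round(runif(100), 2)))
  th <- seq(0, 1, by = 0.1)
  roc <- roc_curve(scores, gold, th, direction = "greater")
  for (i in seq_along(th)) {
    fl <- scores[!is.na(scores$score) & scores$score > th[i], ]
    m <- suppressWarnings(classify_signals(fl, uni, gold))
    expect_equal(roc$sensitivity[i], m$sensitivity)
    expect_equal(roc$one_minus_specificity[i], 1 - m$specificity)
  }
  # monotone thresholds give monotone operating points
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$one_minus_specificity) <= 0))
})

test_that("pairs without scores cap attainable sensitivity below one", {
  uni <- tibble::tibble(vaccine = "V1", event = paste0("E", 1:10))
  gold <- as_gold_standard(uni)           # every pair is a true signal
  scores <- dplyr::mutate(uni, score = c(rep(NA, 4), runif(6)))
  roc <- roc_curve(scores, gold, thresholds = c(1.01), direction = "less")
  expect_equal(roc$sensitivity, 0.6)      # NA-score pairs never flagged
})

test_that("the benchmark table joins overall metrics with median ranks", {
  db <- fixture_db()
  uni <- dplyr::distinct(db$reports[c("vaccine", "event")])
  f1 <- tidy(tto_scan(db$reports, alpha = 0.5, window_days = 90))
  f2 <- tidy(mgps_flag(run_mgps(db$reports, "U"), 1))
  flags <- dplyr::bind_rows(
    TTO = f1[f1$flagged, c("vaccine", "event")],
    MGPS = f2[f2$flagged, c("vaccine", "event")],
    .id = "algorithm")
  suppressWarnings(suppressMessages(
    bm <- benchmark_algorithms(flags, uni, db$gold)))
  expect_setequal(bm$algorithm, c("TTO", "MGPS"))
  expect_true(all(c("median_rank", "ppv", "tp", "specificity") %in% names(bm)))
  expect_equal(order(bm$median_rank), seq_len(nrow(bm)))
})

test_that("both detectors' ROC curves dominate the diagonal on dual signals", {
  # signals that are both disproportionate and onset-clustered, on a grid
  # with uniform margins so baseline expectations are known
  sig <- tibble::tibble(
    vaccine = sprintf("V%02d", c(1, 3, 5, 7, 9, 10)),
    event = sprintf("E%03d", c(4, 11, 19, 27, 33, 41)),
    rel_rate = 10, tto_profile = "clustered", mode_days = 2)
  db <- simulate_database(sim_config(
    n_vaccines = 10, n_events = 50, n_reports = 8000,
    vaccine_prop = rep(1, 10), event_prop = rep(1, 50),
    signals = sig, seed = 19))
  labelled <- paste(sig$vaccine, sig$event)

  auc_rank <- function(score, pos) {
    # Mann-Whitney AUC; NA scores rank lowest (never flagged)
    score[is.na(score)] <- -Inf
    r <- rank(score)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
      (sum(pos) * sum(!pos))
  }
  boot_ci_low <- function(score, pos, reps = 200) {
    stats::quantile(vapply(seq_len(reps), function(i) {
      idx <- sample(length(score), replace = TRUE)
      auc_rank(score[idx], pos[idx])
    }, numeric(1)), 0.025)
  }

  fit <- run_mgps(db$reports, "U")
  pos_m <- paste(fit$results$vaccine, fit$results$event) %in% labelled
  expect_equal(sum(pos_m), 6)
  set.seed(20)
  expect_gt(boot_ci_low(fit$results$eb05, pos_m), 0.5)

  scan <- tto_scan(db$reports, alpha = 0.01, window_days = 60)
  r <- tidy(scan)
  score_t <- -pmax(r$p_events, r$p_vaccines)   # higher = stronger signal
  pos_t <- paste(r$vaccine, r$event) %in% labelled
  expect_gt(boot_ci_low(score_t, pos_t), 0.5)
})
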