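test_that("window filtering includes both boundaries and drops missing", {
  r <- mk_reports(rep("V1", 4), rep("E1", 4), tto = c(0L, 30L, 31L, NA))
  expect_equal(sort(tto_sample(r, "V1", "E1", 30)), c(0L, 30L))
  expect_equal(tto_sample(r, "V1", "E1", 90), c(0L, 30L, 31L))
  r_na <- mk_reports(rep("V1", 3), rep("E1", 3), tto = NA)
  expect_length(tto_sample(r_na, "V1", "E1", 30), 0)
})

test_that("backgrounds exclude the target pair and split by axis", {
  r <- mk_reports(c("V1", "V1", "V1", "V2", "V3", "V2"),
                  c("E1", "E1", "E2", "E1", "E1", "E2"),
                  tto = c(1L, 2L, 3L, 4L, 5L, 6L))
  bg <- tto_backgrounds(r, "V1", "E1", 30)
  expect_equal(sort(bg$between_events), 3L)
  expect_equal(sort(bg$between_vaccines), c(4L, 5L))
  # database of a single pair: both backgrounds empty
  one <- mk_reports(c("V1", "V1"), "E1", tto = c(1L, 2L))
  bg1 <- tto_backgrounds(one, "V1", "E1", 30)
  expect_length(bg1$between_events, 0)
  expect_length(bg1$between_vaccines, 0)
})

test_that("backgrounds match a brute-force filter on the fixture", {
  db <- fixture_db()
  w <- 60
  r <- db$reports
  inw <- !is.na(r$tto_days) & r$tto_days >= 0 & r$tto_days <= w
  pairs <- head(dplyr::distinct(r[c("vaccine", "event")]), 20)
  for (i in seq_len(nrow(pairs))) {
    v <- pairs$vaccine[i]; e <- pairs$event[i]
    bg <- tto_backgrounds(r, v, e, w)
    expect_equal(sort(bg$between_events),
                 sort(r$tto_days[inw & r$vaccine == v & r$event != e]))
    expect_equal(sort(bg$between_vaccines),
                 sort(r$tto_days[inw & r$event == e & r$vaccine != v]))
    expect_equal(sort(tto_sample(r, v, e, w)),
                 sort(r$tto_days[inw & r$vaccine == v & r$event == e]))
  }
})

test_that("the KS statistic handles identity, separation and hand examples", {
  ks0 <- ks_two_sample(c(1, 1, 2, 5), c(5, 2, 1, 1))
  expect_equal(ks0$statistic, 0)
  expect_equal(ks0$p_value, 1)
  ks1 <- ks_two_sample(c(1, 2, 3), c(10, 11))
  expect_equal(ks1$statistic, 1)
  ks2 <- ks_two_sample(c(1, 2, 3), c(1, 2, 3, 10))
  expect_equal(ks2$statistic, 0.25)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("KS equals the exhaustive pooled-ECDF scan and is symmetric", {
  set.seed(31)
  for (rep in 1:60) {
    n1 <- sample(2:60, 1); n2 <- sample(2:60, 1)
    x <- sample(0:20, n1, replace = TRUE)   # tie-heavy integer days
    y <- sample(0:20, n2, replace = TRUE)
    ks <- ks_two_sample(x, y)
    expect_equal(ks$statistic, bf_ks_D(x, y), tolerance = 1e-12)
    # symmetry and invariance under a strictly monotone transform
    expect_equal(ks_two_sample(y, x)$statistic, ks$statistic)
    expect_equal(ks_two_sample(exp(x / 5), exp(y / 5))$statistic,
                 ks$statistic)
  }
})

test_that("asymptotic p-values agree with the reference implementation", {
  set.seed(8)
  for (rep in 1:25) {
    x <- rnorm(sample(10:60, 1))
    y <- rnorm(sample(10:60, 1), mean = 0.4)   # tie-free continuous data
    ks <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(ks$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ks$p_value, ref$p.value, tolerance = 1e-4)
  }
  # exact conditional p under ties matches psmirnov directly
  x <- c(0L, 0L, 1L, 3L, 3L); y <- c(0L, 2L, 3L, 3L)
  ks <- ks_two_sample(x, y, exact = TRUE)
  expect_equal(ks$p_value,
               1 - stats::psmirnov(ks$statistic, sizes = c(5, 4),
                                   z = sort(c(x, y)), exact = TRUE))
})

test_that("the time-to-onset grid has 18 uniquely labelled configs", {
  g <- tto_grid()
  expect_equal(nrow(g), 18)
  expect_equal(dplyr::n_distinct(g$label), 18)
  expect_true(all(c("TTO-01-60", "TTO-20-90", "TTO-99-30") %in% g$label))
  expect_setequal(unique(g$alpha), c(0.01, 0.05, 0.10, 0.20, 0.50, 0.99))
  expect_setequal(unique(g$window_days), c(30L, 60L, 90L))
})

test_that("flagging requires data, both backgrounds and dual significance", {
  # target clustered at day 2, backgrounds spread over the window
  set.seed(12)
  r <- dplyr::bind_rows(
    mk_reports(rep("V1", 200), "E1", tto = 2L),
    mk_reports(rep("V1", 200), "E2", tto = sample(0:60, 200, TRUE),
               id = "B1"),
    mk_reports(rep("V2", 200), "E1", tto = sample(0:60, 200, TRUE),
               id = "B2"))
  row <- tto_flag_pair(r, "V1", "E1", alpha = 0.01, window_days = 60)
  expect_identical(row$status, "OK")
  expect_true(row$flagged)
  expect_lt(row$p_events, 1e-4)
  # empty target sample
  row2 <- tto_flag_pair(r, "V1", "E3", alpha = 0.01, window_days = 60)
  expect_identical(row2$status, "INSUFFICIENT_TARGET")
  expect_false(row2$flagged)
  # missing background
  solo <- mk_reports(c("V9", "V9"), "E9", tto = c(1L, 2L))
  row3 <- tto_flag_pair(dplyr::bind_rows(r, solo), "V9", "E9",
                        alpha = 0.5, window_days = 60)
  expect_identical(row3$status, "INSUFFICIENT_BACKGROUND")
  # min_target guard
  row4 <- tto_flag_pair(r, "V1", "E1", alpha = 0.01, window_days = 60,
                        min_target = 1000)
  expect_identical(row4$status, "INSUFFICIENT_TARGET")
})

test_that("the flagged set is monotone in alpha at fixed window", {
  db <- fixture_db()
  alphas <- c(0.01, 0.05, 0.10, 0.20, 0.50, 0.99)
  prev <- NULL
  for (a in alphas) {
    cur <- with(tidy(tto_scan(db$reports, alpha = a, window_days = 60)),
                paste(vaccine, event)[flagged])
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("a scan result is internally consistent", {
  db <- fixture_db()
  scan <- tto_scan(db$reports, alpha = 0.2, window_days = 90)
  r <- tidy(scan)
  expect_true(all(r$flagged[r$status != "OK"] == FALSE))
  ok <- r$status == "OK"
  expect_true(all(r$flagged[ok] ==
                    (r$p_events[ok] < 0.2 & r$p_vaccines[ok] < 0.2)))
  expect_true(all(r$D_events[ok] >= 0 & r$D_events[ok] <= 1))
  expect_equal(nrow(r),
               nrow(dplyr::distinct(db$reports[c("vaccine", "event")])))
})
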