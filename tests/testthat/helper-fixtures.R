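# Shared fixture builders.  Everything is generated in code; nothing is read
# from disk except through the package's own writers.

# quick report-row builder with sensible defaults
mk_reports <- function(vaccine, event, tto = NA_integer_,
                       sex = "F", age = 30, region = "EU",
                       date = as.Date("2009-06-15"), id = NULL) {
  k <- max(length(vaccine), length(event), length(tto), length(date))
  date <- rep_len(as.Date(date), k)
  tibble::tibble(
    report_id = if (is.null(id)) sprintf("R%04d", seq_len(k)) else rep_len(id, k),
    receipt_date = date,
    vaccine = rep_len(vaccine, k),
    event = rep_len(event, k),
    sex = rep_len(sex, k),
    age_years = rep_len(as.numeric(age), k),
    region = rep_len(region, k),
    report_year = as.integer(format(date, "%Y")),
    tto_days = rep_len(as.integer(tto), k))
}

# memoised reference fixture (deterministic; ~2300 rows)
fixture_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- table_like_fixture()
    cache
  }
})

# brute-force two-sample KS statistic: exhaustive scan over pooled values
bf_ks_D <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  max(vapply(pooled, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}
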