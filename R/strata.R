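#' Stratification specifications
#'
#' A stratum specification selects a subset of the four stratification
#' factors -- (S)ex, (A)ge, (R)egion and (Y)ear of reporting -- together with
#' the age intervals used for the A factor.  The sixteen admissible
#' specifications (the empty set "U" through the full "SARY") are the
#' stratification arms of the disproportionality grid.
#'
#' Unknown factor values form their own stratum level (`"UNK"`) rather than
#' being dropped, so cell counts are conserved between stratified and
#' unstratified runs.
#'
#' @param factors A string of factor letters in any order (e.g. `"SARY"`,
#'   `"AY"`) or `"U"` for unstratified.
#' @param age_bins Increasing numeric vector of right-open age interval
#'   breakpoints covering `[0, Inf)`; the default
#'   `c(0, 2, 12, 18, 46, 66, Inf)` separates infant, child, adolescent and
#'   adult vaccine target populations.
#' @return An object of class `stratum_spec` with elements `factors`,
#'   `age_bins` and canonical `label`.
#' @export
#' @examples
#' stratum_spec("SARY")
#' stratum_spec("U")
stratum_spec <- function(factors = "SARY", age_bins = c(0, 2, 12, 18, 46, 66, Inf)) {
  stopifnot(is.character(factors), length(factors) == 1)
  letters_in <- if (toupper(factors) %in% c("U", "")) character(0) else
    strsplit(toupper(factors), "")[[1]]
  bad <- setdiff(letters_in, c("S", "A", "R", "Y"))
  if (length(bad) > 0 || anyDuplicated(letters_in)) {
    stop("factors must be 'U' or distinct letters from S, A, R, Y", call. = FALSE)
  }
  if (age_bins[1] != 0 || !all(diff(age_bins) > 0) || !is.infinite(age_bins[length(age_bins)])) {
    stop("age_bins must increase from 0 to Inf", call. = FALSE)
  }
  fac <- intersect(c("S", "A", "R", "Y"), letters_in)  # canonical SARY order
  structure(
    list(factors = fac, age_bins = age_bins,
         label = if (length(fac) == 0) "U" else paste(fac, collapse = "")),
    class = "stratum_spec")
}

#' @export
print.stratum_spec <- function(x, ...) {
  cat("<stratum_spec> ", x$label, "\n", sep = "")
  if ("A" %in% x$factors) {
    cat("  age bins: ", paste(age_bin_labels(x$age_bins), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' The sixteen admissible stratification labels
#'
#' @return Character vector `c("U","S","A","R","Y","SA",...,"SARY")`.
#' @export
all_stratifications <- function() {
  c("U", "S", "A", "R", "Y",
    "SA", "SR", "SY", "AR", "AY", "RY",
    "SAR", "SAY", "ARY", "SRY", "SARY")
}

## "0-1", "2-11", ..., "66+" labels for right-open integer-year bins
age_bin_labels <- function(breaks) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  ifelse(is.infinite(hi), paste0(format(lo, trim = TRUE), "+"),
         sprintf("%s-%s", format(lo, trim = TRUE), format(hi - 1, trim = TRUE)))
}

#' Assign each report to a stratum
#'
#' Concatenates the levels of the selected stratification factors with `"|"`.
#' Unknown sex/age/region map to the `"UNK"` level of their factor; with no
#' factors selected every report falls in the single global stratum `"ALL"`.
#'
#' @param reports A reports tibble.
#' @param spec A [stratum_spec()].
#' @return Character vector of stratum labels, one per report row.
#' @export
#' @examples
#' r <- tibble::tibble(report_id = "R1", receipt_date = as.Date("2009-06-01"),
#'                     vaccine = "V1", event = "E1", sex = "F", age_years = 15,
#'                     region = "EU", report_year = 2009L, tto_days = 2L)
#' assign_stratum(r, stratum_spec("SARY"))  # "F|12-17|EU|2009"
assign_stratum <- function(reports, spec = stratum_spec()) {
  stopifnot(inherits(spec, "stratum_spec"))
  n <- nrow(reports)
  if (length(spec$factors) == 0) return(rep("ALL", n))
  parts <- lapply(spec$factors, function(f) {
    switch(f,
      S = ifelse(is.na(reports$sex), "UNK", reports$sex),
      A = {
        idx <- findInterval(reports$age_years, spec$age_bins)
        lab <- age_bin_labels(spec$age_bins)[idx]
        ifelse(is.na(reports$age_years), "UNK", lab)
      },
      R = ifelse(is.na(reports$region), "UNK", reports$region),
      Y = as.character(reports$report_year))
  })
  do.call(paste, c(parts, sep = "|"))
}

#' Aggregate reports into stratified vaccine-event pair counts
#'
#' Tallies N, the number of report rows for each (vaccine, event, stratum)
#' cell, together with the per-stratum margins needed for expected counts:
#' row totals per vaccine, column totals per event and stratum grand totals.
#' One report row contributes exactly 1 to exactly one cell, so the sum of
#' all cells equals `nrow(reports)` under every stratification.
#'
#' @param reports A reports tibble (non-empty).
#' @param spec A [stratum_spec()].
#' @return An object of class `pair_counts`: a list with tibbles `cells`
#'   (`vaccine`, `event`, `stratum`, `n`), `vaccine_margin`, `event_margin`,
#'   `stratum_margin`, and the `spec`.
#' @seealso [expected_counts()]
#' @export
build_pair_counts <- function(reports, spec = stratum_spec()) {
  if (nrow(reports) == 0) stop("no reports to count", call. = FALSE)
  df <- tibble::tibble(vaccine = reports$vaccine, event = reports$event,
                       stratum = assign_stratum(reports, spec))
  cells <- dplyr::count(df, .data$vaccine, .data$event, .data$stratum, name = "n")
  structure(list(
    cells = cells,
    vaccine_margin = dplyr::count(cells, .data$vaccine, .data$stratum,
                                  wt = .data$n, name = "n_vaccine"),
    event_margin = dplyr::count(cells, .data$event, .data$stratum,
                                wt = .data$n, name = "n_event"),
    stratum_margin = dplyr::count(cells, .data$stratum, wt = .data$n,
                                  name = "n_total"),
    spec = spec
  ), class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("<pair_counts> stratification ", x$spec$label, ": ",
      nrow(dplyr::distinct(x$cells, .data$vaccine, .data$event)), " pairs, ",
      nrow(x$stratum_margin), " strata, ",
      sum(x$cells$n), " report rows\n", sep = "")
  invisible(x)
}
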