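#' Read a spontaneous-report table
#'
#' Reads a delimited file of spontaneous vaccine adverse-event reports, one
#' row per vaccine--event mention (a case reporting several events yields
#' several rows sharing a `report_id`).  Expected columns are `report_id`,
#' `receipt_date`, `vaccine`, `event`, `sex`, `age_years`, `region` and
#' `tto_days` (time-to-onset, in days between immunisation and event onset).
#' `report_year` is always derived from `receipt_date`.
#'
#' Rows whose mandatory fields (`vaccine`, `event`, `receipt_date`) cannot be
#' parsed, or whose `tto_days` is negative, are dropped; the counts of dropped
#' rows by reason are attached as the `"rejections"` attribute and summarised
#' in a message.  Unknown sex/age/region and missing time-to-onset are coded
#' `NA` (parsed from the tokens in `na`).
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `NULL` (default) sniffs comma vs tab from the
#'   header line.
#' @param na Character vector of tokens read as missing/unknown.
#' @return A tibble of validated reports with columns `report_id` (character),
#'   `receipt_date` (Date), `vaccine`, `event` (character), `sex` (`"F"`,
#'   `"M"` or `NA`), `age_years` (double or `NA`), `region` (character or
#'   `NA`), `report_year` (integer), `tto_days` (integer or `NA`), plus a
#'   `"rejections"` attribute (tibble of `reason`, `n`).
#' @seealso [write_reports()], [read_gold_standard()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "report_id,receipt_date,vaccine,event,sex,age_years,region,tto_days",
#'   "R1,2009-03-02,V1,E1,F,15,EU,2",
#'   "R1,2009-03-02,V1,E2,F,15,EU,",
#'   "R2,2008-11-20,V2,E1,M,,NA,40"), path)
#' read_reports(path)
read_reports <- function(path, delim = NULL, na = c("", "NA")) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, na = na,
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE)
  required <- c("report_id", "receipt_date", "vaccine", "event",
                "sex", "age_years", "region", "tto_days")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("reports file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_reports(raw)
}

## Coerce a raw character tibble to the typed report schema, dropping invalid
## rows and recording why.  Shared by read_reports() and as_reports().
validate_reports <- function(raw) {
  date <- as.Date(suppressWarnings(
    readr::parse_date(as.character(raw$receipt_date), format = "%Y-%m-%d")))
  age <- suppressWarnings(as.numeric(raw$age_years))
  tto <- suppressWarnings(as.integer(round(as.numeric(raw$tto_days))))
  sex <- toupper(as.character(raw$sex))
  sex[!sex %in% c("F", "M")] <- NA_character_

  bad_vaccine <- is.na(raw$vaccine) | raw$vaccine == ""
  bad_event <- is.na(raw$event) | raw$event == ""
  bad_date <- is.na(date)
  # negative onset delay violates the data model; row-level rejection
  bad_tto <- !is.na(tto) & tto < 0
  bad <- bad_vaccine | bad_event | bad_date | bad_tto

  rejections <- tibble::tibble(
    reason = c("missing vaccine", "missing event", "unparseable receipt_date",
               "negative tto_days"),
    n = c(sum(bad_vaccine), sum(bad_event), sum(bad_date & !bad_vaccine & !bad_event),
          sum(bad_tto & !bad_vaccine & !bad_event & !bad_date))
  )
  rejections <- rejections[rejections$n > 0, , drop = FALSE]
  if (nrow(rejections) > 0) {
    message(sum(bad), " row(s) rejected: ",
            paste(sprintf("%s (%d)", rejections$reason, rejections$n),
                  collapse = ", "))
  }

  out <- tibble::tibble(
    report_id = as.character(raw$report_id),
    receipt_date = date,
    vaccine = as.character(raw$vaccine),
    event = as.character(raw$event),
    sex = sex,
    age_years = age,
    region = as.character(raw$region),
    report_year = as.integer(format(date, "%Y")),
    tto_days = tto
  )[!bad, , drop = FALSE]
  attr(out, "rejections") <- rejections
  out
}

#' Write a spontaneous-report table
#'
#' Writes reports in the same delimited layout [read_reports()] expects, so
#' that a write/read round trip is the identity on the report fields.
#' `NA` fields are written as empty strings.
#'
#' @param reports A reports tibble (see [read_reports()]).
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, delim = ",") {
  cols <- c("report_id", "receipt_date", "vaccine", "event",
            "sex", "age_years", "region", "tto_days")
  readr::write_delim(reports[cols], path, delim = delim, na = "",
                     progress = FALSE)
  invisible(path)
}

#' Read a gold-standard label file
#'
#' The gold standard maps each vaccine to the set of event codes considered
#' truly associated (in practice, the adverse reactions listed in the
#' product's label, mapped to event codes).  It is read from a two-column
#' delimited file (`vaccine`, `event`), one labelled pair per row; duplicate
#' rows collapse to one.
#'
#' Vaccines absent from the file are *not covered*: pairs involving them
#' cannot be evaluated and [classify_signals()] excludes them (distinct from
#' "not labelled").
#'
#' @param path Path to a two-column delimited file with a header row.
#' @param delim Field delimiter; `NULL` sniffs comma vs tab.
#' @return A tibble with columns `vaccine` and `event`, one row per labelled
#'   pair, of class `"gold_standard"`.
#' @export
read_gold_standard <- function(path, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE)
  if (!all(c("vaccine", "event") %in% names(raw))) {
    stop("gold-standard file must have columns 'vaccine' and 'event'",
         call. = FALSE)
  }
  gold <- as_gold_standard(raw)
  if (nrow(gold) == 0) {
    stop("gold-standard file is empty: evaluation is impossible", call. = FALSE)
  }
  gold
}

#' Coerce a data frame to a gold standard
#'
#' @param x A data frame with `vaccine` and `event` columns.
#' @return A deduplicated `gold_standard` tibble.
#' @rdname read_gold_standard
#' @export
as_gold_standard <- function(x) {
  out <- dplyr::distinct(
    dplyr::filter(tibble::as_tibble(x)[c("vaccine", "event")],
                  !is.na(.data$vaccine), !is.na(.data$event)))
  class(out) <- c("gold_standard", class(out))
  out
}

#' Write a gold standard to a two-column delimited file
#'
#' @param gold A `gold_standard` tibble (or any vaccine/event data frame).
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @rdname read_gold_standard
#' @export
write_gold_standard <- function(gold, path, delim = ",") {
  readr::write_delim(tibble::as_tibble(gold)[c("vaccine", "event")], path,
                     delim = delim, progress = FALSE)
  invisible(path)
}

#' Look up gold-standard status of vaccine-event pairs
#'
#' @param gold A `gold_standard` tibble.
#' @param vaccine,event Character vectors (recycled to common length).
#' @return Logical vector: `TRUE` if labelled, `FALSE` if the vaccine is
#'   covered but the pair unlabelled, `NA` if the vaccine is not covered by
#'   the gold standard.
#' @export
gold_lookup <- function(gold, vaccine, event) {
  covered <- vaccine %in% unique(gold$vaccine)
  key <- paste(vaccine, event, sep = "\r")
  labelled <- key %in% paste(gold$vaccine, gold$event, sep = "\r")
  ifelse(covered, labelled, NA)
}
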