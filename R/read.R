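#' Read event-level clinical records
#'
#' Reads a delimited text file of coded clinical events, one row per event.
#' The file must contain (at least) the columns `person_id`, `concept_id`,
#' `event_date` and `domain`; alternative column names can be supplied via
#' `columns`. Dates must be ISO-8601 (`YYYY-MM-DD`).
#'
#' @param path path to a CSV/TSV file (delimiter auto-detected unless `sep`
#'   is given).
#' @param columns named character vector mapping the canonical names
#'   (`person_id`, `concept_id`, `event_date`, `domain`) to the file's column
#'   names. Defaults to the canonical names themselves.
#' @param sep field delimiter; `"auto"` lets the reader sniff it.
#' @return a `data.table` with columns `person_id` (character), `concept_id`
#'   (character), `event_date` (`Date`) and `domain` (character), in file
#'   order.
#' @export
read_events <- function(path, columns = NULL, sep = "auto") {
  if (!file.exists(path)) stop_arg("event file not found: ", path)
  cols <- c(person_id = "person_id", concept_id = "concept_id",
            event_date = "event_date", domain = "domain")
  if (!is.null(columns)) cols[names(columns)] <- columns
  dt <- data.table::fread(path, sep = sep, colClasses = "character",
                          showProgress = FALSE)
  missing_cols <- setdiff(unname(cols), names(dt))
  if (length(missing_cols))
    stop_arg("event file is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
  out <- dt[, unname(cols), with = FALSE]
  data.table::setnames(out, names(cols))
  if (nrow(out)) {
    if (any(!nzchar(out$concept_id)))
      stop_arg("empty concept_id at row(s): ",
               paste(head(which(!nzchar(out$concept_id)), 5L), collapse = ", "))
    dates <- as.Date(out$event_date, format = "%Y-%m-%d")
    bad <- which(is.na(dates))
    if (length(bad))
      stop_arg("unparseable event_date at row(s): ",
               paste(head(bad, 5L), collapse = ", "),
               " (value '", out$event_date[bad[1L]], "')")
    out[, event_date := dates]
  } else {
    out[, event_date := as.Date(character())]
  }
  out[]
}

#' Read a prediction cohort
#'
#' Reads the cohort table anchoring each observation: one row per
#' (person, index date) with a precomputed binary outcome label for the
#' time-at-risk window, plus age and sex.
#'
#' @param path path to a delimited file with columns `person_id`,
#'   `index_date`, `outcome`, `age_years`, `sex`.
#' @param allow_duplicates keep duplicated (person_id, index_date) rows
#'   instead of erroring.
#' @param sep field delimiter, `"auto"` to sniff.
#' @return a `data.table` with typed columns and an `observation_id` key
#'   (`<person_id>@<index_date>` made unique); attribute `prevalence` holds
#'   the outcome rate.
#' @export
read_cohort <- function(path, allow_duplicates = FALSE, sep = "auto") {
  if (!file.exists(path)) stop_arg("cohort file not found: ", path)
  dt <- data.table::fread(path, sep = sep, colClasses = "character",
                          showProgress = FALSE)
  need <- c("person_id", "index_date", "outcome", "age_years", "sex")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop_arg("cohort file is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
  out <- dt[, need, with = FALSE]
  validate_cohort(out, allow_duplicates = allow_duplicates)
}

## shared validation so in-memory cohorts (e.g. simulated) get the same checks
validate_cohort <- function(out, allow_duplicates = FALSE) {
  out <- data.table::as.data.table(out)
  dates <- as.Date(as.character(out$index_date), format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad))
    stop_arg("unparseable index_date at row(s): ",
             paste(head(bad, 5L), collapse = ", "))
  out[, index_date := dates]
  y <- suppressWarnings(as.numeric(out$outcome))
  if (any(is.na(y)) || !is_binary01(y))
    stop_arg("outcome must be binary 0/1; offending row(s): ",
             paste(head(which(is.na(y) | !(y %in% c(0, 1))), 5L), collapse = ", "))
  out[, outcome := as.integer(y)]
  age <- suppressWarnings(as.numeric(out$age_years))
  if (any(is.na(age) | age < 0)) stop_arg("age_years must be non-negative numbers")
  out[, age_years := age]
  sex <- tolower(as.character(out$sex))
  if (!all(sex %in% c("female", "male")))
    stop_arg("sex must be 'female' or 'male'")
  out[, sex := sex]
  out[, person_id := as.character(person_id)]
  dup <- duplicated(out[, c("person_id", "index_date")])
  if (any(dup) && !allow_duplicates)
    stop_arg("duplicate (person_id, index_date) rows at: ",
             paste(head(which(dup), 5L), collapse = ", "),
             " (set allow_duplicates = TRUE to keep)")
  out[, observation_id := make.unique(paste0(person_id, "@", format(index_date)))]
  data.table::setattr(out, "prevalence", mean(out$outcome))
  out[]
}
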