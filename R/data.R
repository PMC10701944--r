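#' Cohort summary statistics for three primary-care prediction problems
#'
#' Aggregate counts for three typical prediction problems on general-practice
#' records — 30-day mortality after a GP visit in over-60s, 30-day hospital
#' readmission in adults, and 5-year dementia onset in patients aged 50-79 —
#' shipped as a worked example of cohort arithmetic. `prevalence_pct` is
#' recomputed from the counts as `100 * outcome_events / observations`;
#' `outcome_pct` is the rounded figure as typically reported.
#'
#' @return a data.frame with columns `problem`, `observations`,
#'   `outcome_events`, `outcome_pct` and the recomputed `prevalence_pct`.
#' @export
cohort_summary <- function() {
  path <- system.file("extdata", "cohort_summary.tsv", package = "ehrattn")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$prevalence_pct <- 100 * df$outcome_events / df$observations
  df
}
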