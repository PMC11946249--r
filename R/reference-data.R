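#' Reference summary tables for the five ALK-TKIs
#'
#' Published summary statistics for crizotinib, ceritinib, alectinib,
#' brigatinib and lorlatinib as reported to FAERS (2011Q1-2023Q4), shipped
#' as plain CSV for worked examples and for validating the package's
#' threshold and classification logic against externally computed values.
#'
#' * `alk_dili_reference()`: per-drug primary-suspect report totals, DILI
#'   report counts and proportions, and the four disproportionality
#'   statistics with their interval bounds for the consolidated DILI event.
#' * `alk_signal_reference()`: selected SOC-level and PT-level signal rows
#'   (report count `n`, ROR with 95% CI, PRR with chi-squared, IC with
#'   IC025, EBGM with EBGM05).
#' * `alk_cohort_reference()`: cohort descriptives (sex, reporter country,
#'   reporter occupation, outcome, time-to-onset bins) as printed counts
#'   and percentages.
#'
#' @return a tibble (layout per function, see above).
#' @name alk_reference
NULL

#' @rdname alk_reference
#' @export
alk_dili_reference <- function() {
  readr::read_csv(
    system.file("extdata", "alk_tki_dili_reference.csv",
                package = "faersignal", mustWork = TRUE),
    col_types = "ciidddddddddd", progress = FALSE)
}

#' @rdname alk_reference
#' @export
alk_signal_reference <- function() {
  readr::read_csv(
    system.file("extdata", "alk_tki_signal_reference.csv",
                package = "faersignal", mustWork = TRUE),
    col_types = "ccciddddddddd", progress = FALSE)
}

#' @rdname alk_reference
#' @export
alk_cohort_reference <- function() {
  readr::read_csv(
    system.file("extdata", "alk_tki_cohort_reference.csv",
                package = "faersignal", mustWork = TRUE),
    col_types = "cccid", na = "NA", progress = FALSE)
}
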