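#' Deduplicate re-submitted case reports
#'
#' Collapses re-submissions of the same safety case to a single report using
#' the FDA-recommended rules: within each `caseid` group keep the report
#' with the latest `fda_dt`; among ties on `fda_dt`, keep the numerically
#' higher `primaryid` (falling back to lexicographic comparison after left
#' zero-padding when ids are not numeric). A report with missing `fda_dt`
#' loses all tie-breaks (treated as earliest) and is tallied.
#'
#' The operation is idempotent and the kept set is returned sorted by
#' `caseid`, so repeated runs are byte-identical.
#'
#' @param cases a case-report tibble from [assemble_cases()] (any data frame
#'   with `caseid`, `primaryid`, `fda_dt` columns works).
#' @return the kept tibble, sorted by `caseid`, with attribute `dedup` — a
#'   list with `removed_count`, `missing_fda_dt` (reports that lost
#'   tie-breaks for lack of a date) and `input_count`.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   caseid = c("1", "1"), primaryid = c("100", "101"),
#'   fda_dt = as.Date(c("2023-01-01", "2023-03-01"))
#' )
#' dedup_cases(x)$primaryid # "101"
dedup_cases <- function(cases) {
  check_that(all(c("caseid", "primaryid", "fda_dt") %in% names(cases)),
             "cases must carry caseid, primaryid and fda_dt")
  n_in <- nrow(cases)
  fda <- parse_faers_date(cases$fda_dt)
  missing_dt <- sum(is.na(fda) & duplicated(cases$caseid) |
                      is.na(fda) & duplicated(cases$caseid, fromLast = TRUE))
  # missing dates sort before every real date
  fda_key <- ifelse(is.na(fda), -Inf, as.numeric(fda))
  pid_key <- primaryid_rank(as.character(cases$primaryid))

  ord <- order(cases$caseid, -fda_key, -pid_key)
  kept <- cases[ord, , drop = FALSE]
  kept <- kept[!duplicated(kept$caseid), , drop = FALSE]
  kept <- kept[order(kept$caseid), , drop = FALSE]

  attr(kept, "dedup") <- list(
    removed_count = n_in - nrow(kept),
    missing_fda_dt = missing_dt,
    input_count = n_in
  )
  kept
}
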