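#' Write a signal table to CSV
#'
#' Renders a [disproportionality()] result in the layout of published
#' signal tables: drug, event, level, N, ROR with 95% CI, PRR with
#' chi-squared, IC with IC025, EBGM with EBGM05 and the per-algorithm
#' flags. All statistics are rounded to 2 decimals, half away from zero
#' (so 11.005 renders "11.01"), and re-reading the file reproduces the
#' values at that precision.
#'
#' @param results nonempty tibble from [disproportionality()] (or any
#'   tibble with those columns).
#' @param path output CSV path.
#' @return invisibly, the formatted tibble that was written.
#' @export
write_signal_table <- function(results, path) {
  check_that(nrow(results) > 0, "results must be nonempty",
             "faersignal_argument_error")
  fmt <- function(x) {
    out <- sprintf("%.2f", round2(x, 2))
    out[is.na(x)] <- ""
    out
  }
  out <- tibble(
    drug = results$drug, event = results$event, level = results$level,
    N = results$a,
    ror = fmt(results$ror),
    ror_ci_low = fmt(results$ror_low), ror_ci_high = fmt(results$ror_high),
    prr = fmt(results$prr), chi2 = fmt(results$chi2),
    ic = fmt(results$ic), ic025 = fmt(results$ic025),
    ebgm = fmt(results$ebgm), ebgm05 = fmt(results$ebgm05),
    ror_flag = results$ror_flag, prr_flag = results$prr_flag,
    bcpnn_flag = results$bcpnn_flag, mgps_flag = results$mgps_flag,
    signal = results$signal)
  writeLines(readr::format_csv(out), path)
  invisible(out)
}

#' Write a cohort profile table to CSV
#'
#' @param profile tibble from [cohort_profile()] or [dili_profile()].
#' @param path output CSV path.
#' @return invisibly, `profile`.
#' @export
write_profile_table <- function(profile, path) {
  out <- profile
  if ("pct" %in% names(out)) out$pct <- round2(out$pct, 2)
  if ("value" %in% names(out)) out$value <- round2(out$value, 2)
  writeLines(readr::format_csv(out), path)
  invisible(profile)
}
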