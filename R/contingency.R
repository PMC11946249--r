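# long (primaryid, event) pairs at the requested level; one row per report
# per distinct event, so a report with two PTs in one SOC counts once there
event_pairs <- function(cases, level, hierarchy) {
  long <- tibble(
    primaryid = rep(cases$primaryid, lengths(cases$pts)),
    event = unlist(cases$pts, use.names = FALSE)
  )
  if (level == "SOC") {
    long$event <- pt_to_soc(long$event, hierarchy)
  }
  distinct(long, .data$primaryid, .data$event)
}

#' Build the 2x2 contingency table for one drug-event pair
#'
#' Counts deduplicated reports into the four cells comparing the target
#' drug (primary-suspect role, canonical `drug` column) against the rest of
#' the ingested dataset: `a` reports with drug and event, `b` with drug
#' only, `c` with event only, `d` with neither. The counting unit is the
#' report: a report listing several qualifying PTs counts once in the event
#' margin, and at SOC level a report qualifies if at least one PT maps to
#' the SOC.
#'
#' @param cases deduplicated case tibble carrying `drug` (see
#'   [add_canonical_drug()]) and the `pts` list-column.
#' @param drug canonical target drug id.
#' @param event target PT name (or SOC name when `level = "SOC"`).
#' @param level `"PT"` or `"SOC"`.
#' @param hierarchy PT-to-SOC map, needed at SOC level.
#' @param comparator `"all"` (default) compares against every other report
#'   in the dataset; `"other_study"` restricts the background to reports of
#'   the other canonical study drugs.
#' @return one-row tibble: `drug`, `event`, `level`, `a`, `b`, `c`, `d`,
#'   `n` (= a+b+c+d), `expected` (= (a+b)(a+c)/n).
#' @export
contingency_table <- function(cases, drug, event, level = c("PT", "SOC"),
                              hierarchy = meddra_hierarchy(),
                              comparator = c("all", "other_study")) {
  level <- match.arg(level)
  comparator <- match.arg(comparator)
  check_that(nrow(cases) > 0, "empty case list", "faersignal_io_error")
  cases <- apply_comparator(cases, drug, comparator)
  tgt_ids <- cases$primaryid[!is.na(cases$drug) & cases$drug == drug]
  if (!length(tgt_ids)) {
    abort(paste0("no reports for drug: ", drug),
          class = "faersignal_lookup_error")
  }
  pairs <- event_pairs(cases, level, hierarchy)
  evt_ids <- unique(pairs$primaryid[pairs$event == event])

  n <- nrow(cases)
  a <- sum(evt_ids %in% tgt_ids)
  b <- length(tgt_ids) - a
  c_ <- length(evt_ids) - a
  d <- n - a - b - c_
  tibble(drug = drug, event = event, level = level,
         a = a, b = b, c = c_, d = d, n = n,
         expected = (a + b) * (a + c_) / n)
}

#' All 2x2 tables for one drug at a level
#'
#' One table per event co-reported with the target drug (`a >= 1`); events
#' never co-reported are omitted. `n` is constant across rows and the `a`
#' values sum to the number of (report, event) pairs for the drug.
#'
#' @inheritParams contingency_table
#' @return tibble with one row per event and the [contingency_table()]
#'   columns.
#' @export
contingency_all <- function(cases, drug, level = c("PT", "SOC"),
                            hierarchy = meddra_hierarchy(),
                            comparator = c("all", "other_study")) {
  level <- match.arg(level)
  comparator <- match.arg(comparator)
  check_that(nrow(cases) > 0, "empty case list", "faersignal_io_error")
  cases <- apply_comparator(cases, drug, comparator)
  is_tgt <- !is.na(cases$drug) & cases$drug == drug
  n_drug <- sum(is_tgt)
  if (!n_drug) {
    abort(paste0("no reports for drug: ", drug),
          class = "faersignal_lookup_error")
  }
  tgt_ids <- cases$primaryid[is_tgt]
  pairs <- event_pairs(cases, level, hierarchy)
  pairs$is_tgt <- pairs$primaryid %in% tgt_ids

  margins <- pairs %>%
    summarise(ac = n(), a = sum(.data$is_tgt), .by = "event") %>%
    filter(.data$a >= 1)

  n <- nrow(cases)
  margins %>%
    mutate(drug = drug, level = level,
           b = n_drug - .data$a,
           c = .data$ac - .data$a,
           d = n - .data$a - .data$b - .data$c,
           n = n,
           expected = (.data$a + .data$b) * (.data$a + .data$c) / n) %>%
    select("drug", "event", "level", "a", "b", "c", "d", "n", "expected") %>%
    arrange(desc(.data$a), .data$event)
}

apply_comparator <- function(cases, drug, comparator) {
  if (comparator == "other_study") {
    cases[!is.na(cases$drug), , drop = FALSE]
  } else {
    cases
  }
}
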