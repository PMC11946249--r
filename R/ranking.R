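#' Rank the top-k adverse event signals
#'
#' Drops PTs matching any exclusion pattern (case-insensitive regular
#' expressions; by default death and COVID-19 terms — a malignancy list is
#' shipped but off by default because disease-progression PTs are routinely
#' ranked in published tables), keeps rows classified as signals, and sorts
#' by report count `a` descending, ties broken by EBGM descending then
#' event name.
#'
#' @param results PT-level tibble from [disproportionality()].
#' @param exclusions named list of pattern vectors ([default_exclusions()]).
#' @param k number of rows to keep; fewer are returned if fewer qualify.
#' @param rule `"all"` keeps rows flagged by all four algorithms (the
#'   combined criterion); `"any"` keeps rows flagged by at least one.
#' @return the ranked tibble, at most `k` rows.
#' @export
top_k_signals <- function(results, exclusions = default_exclusions(),
                          k = 30, rule = c("all", "any")) {
  rule <- match.arg(rule)
  check_that(length(k) == 1 && !is.na(k) && k >= 1,
             "`k` must be a positive integer", "faersignal_argument_error")
  pats <- unlist(exclusions, use.names = FALSE)
  if (length(pats)) {
    drop <- Reduce(`|`, lapply(pats, function(p) {
      grepl(p, results$event, ignore.case = TRUE)
    }))
    results <- results[!drop, , drop = FALSE]
  }
  keep <- if (rule == "all") {
    results$signal
  } else {
    results$ror_flag | results$prr_flag | results$bcpnn_flag | results$mgps_flag
  }
  results %>%
    filter(keep) %>%
    arrange(desc(.data$a), desc(.data$ebgm), .data$event) %>%
    slice_head(n = as.integer(k))
}

#' Cross-drug signal overlap counts
#'
#' For every nonempty subset of drugs, counts the events signalled in
#' exactly that subset — the region counts of a Venn diagram. Counts sum to
#' the size of the union of all signal sets.
#'
#' @param signal_sets named list (at most 6 drugs) of character vectors of
#'   signalled event names.
#' @return tibble with columns `drugs` (subset label, `&`-separated),
#'   `n_drugs`, `count`, and `events` (list-column of member events),
#'   one row per nonempty subset.
#' @export
#' @examples
#' signal_overlap(list(A = c("x", "y"), B = c("y", "z")))
signal_overlap <- function(signal_sets) {
  check_that(length(signal_sets) >= 1 && length(signal_sets) <= 6,
             "signal_overlap supports 1 to 6 drugs")
  drugs <- names(signal_sets)
  universe <- sort(unique(unlist(signal_sets, use.names = FALSE)))
  membership <- vapply(
    universe,
    function(ev) paste(drugs[vapply(signal_sets, function(s) ev %in% s,
                                    logical(1))], collapse = "&"),
    character(1))

  subsets <- unlist(lapply(seq_along(drugs), function(m) {
    combn(drugs, m, FUN = paste, collapse = "&", simplify = FALSE)
  }))
  counts <- unname(vapply(subsets, function(s) sum(membership == s),
                          integer(1)))
  events <- lapply(subsets, function(s) unname(universe[membership == s]))
  tibble(drugs = unlist(subsets),
         n_drugs = lengths(strsplit(unlist(subsets), "&", fixed = TRUE)),
         count = counts,
         events = events)
}

#' Combined DILI association across drugs
#'
#' A drug is classified as DILI-associated when its consolidated DILI event
#' meets the combined four-algorithm criterion.
#'
#' @param dili_results tibble with one row per drug carrying `drug` and the
#'   `signal` flag for the DILI event (e.g. [disproportionality()] output
#'   filtered to `event == "DILI"`, or [signal_flags()] applied to
#'   externally reported statistics).
#' @return tibble with columns `drug`, `dili_associated`.
#' @export
combined_dili_assessment <- function(dili_results) {
  check_that(all(c("drug", "signal") %in% names(dili_results)),
             "dili_results must carry `drug` and `signal` columns")
  dili_results %>%
    distinct(.data$drug, .keep_all = TRUE) %>%
    mutate(dili_associated = .data$signal) %>%
    select("drug", "dili_associated")
}
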