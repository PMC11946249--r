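#' Drug-name dictionary
#'
#' Loads a dictionary mapping verbatim drug-name spellings (generic and
#' brand) to canonical drug ids. The packaged default covers the five ALK
#' tyrosine kinase inhibitors and their US/EU brand names. Matching is
#' case-insensitive and whitespace-normalized, so the dictionary stores one
#' row per spelling.
#'
#' @param path optional CSV with columns `drug`, `spelling`; defaults to the
#'   packaged ALK-TKI dictionary.
#' @return tibble with columns `drug`, `spelling` (normalized to lower case).
#' @export
drug_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "alk_tki_drug_dictionary.csv",
                                package = "faersignal", mustWork = TRUE)
  check_that(file.exists(path), paste0("file not found: ", path),
             "faersignal_io_error")
  dict <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  dict$spelling <- normalize_name(dict$spelling)
  check_that(!anyDuplicated(dict$spelling),
             "invariant violated: spellings must be disjoint across drugs")
  dict
}

normalize_name <- function(x) {
  stringr::str_squish(tolower(x))
}

#' Canonicalize verbatim drug names
#'
#' Case-insensitive, whitespace-normalized exact match against the
#' dictionary spellings. Unmatched names return `NA` (a valid outcome:
#' most of the database is non-study drugs).
#'
#' @param verbatim character vector of verbatim drug names.
#' @param dict a [drug_dictionary()] tibble.
#' @return character vector of canonical ids, `NA` where unmatched.
#' @export
#' @examples
#' canonicalize_drug(c("XALKORI", "crizotinib ", "oxaliplatin"))
canonicalize_drug <- function(verbatim, dict = drug_dictionary()) {
  dict$drug[match(normalize_name(verbatim), dict$spelling)]
}

#' Attach canonical PS-drug ids to assembled cases
#'
#' Adds a `drug` column holding the canonical id of each report's
#' primary-suspect drug (`NA` for non-study drugs).
#'
#' @param cases tibble from [assemble_cases()].
#' @inheritParams canonicalize_drug
#' @return `cases` with an added `drug` column.
#' @export
add_canonical_drug <- function(cases, dict = drug_dictionary()) {
  mutate(cases, drug = canonicalize_drug(.data$ps_drug, dict))
}

#' MedDRA PT-to-SOC hierarchy
#'
#' Loads a flat Preferred Term to System Organ Class map. MedDRA itself is
#' licensed, so the packaged default is a synthetic hierarchy covering the
#' package's simulation vocabulary and DILI lexicon; supply your own export
#' (CSV columns `pt`, `soc`) for real analyses.
#'
#' @param path optional CSV path with columns `pt`, `soc`.
#' @return tibble with columns `pt` (lower case), `soc`.
#' @export
meddra_hierarchy <- function(path = NULL) {
  path <- path %||% system.file("extdata", "meddra_pt_soc_synthetic.csv",
                                package = "faersignal", mustWork = TRUE)
  check_that(file.exists(path), paste0("file not found: ", path),
             "faersignal_io_error")
  h <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  h$pt <- normalize_name(h$pt)
  check_that(!anyDuplicated(h$pt),
             "invariant violated: each PT must map to exactly one SOC")
  h
}

#' Map PTs to their System Organ Class
#'
#' @param pt character vector of PT names.
#' @param hierarchy a [meddra_hierarchy()] tibble.
#' @param strict error on PTs absent from the hierarchy (default); when
#'   `FALSE`, unknown PTs map to `NA` so the caller can collect them.
#' @return character vector of SOC names.
#' @export
#' @examples
#' pt_to_soc("photopsia") # "eye disorders"
pt_to_soc <- function(pt, hierarchy = meddra_hierarchy(), strict = TRUE) {
  soc <- hierarchy$soc[match(normalize_name(pt), hierarchy$pt)]
  if (strict && anyNA(soc)) {
    bad <- unique(pt[is.na(soc)])
    abort(paste0("PT(s) absent from hierarchy: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "faersignal_mapping_error")
  }
  soc
}

#' Liver-injury PT lexicon
#'
#' The set of MedDRA Preferred Terms consolidated into the unified "DILI"
#' event before drug search and counting. The packaged default lists ~40
#' laboratory and clinical liver-injury terms (transaminase/bilirubin
#' elevations, hepatic failure, hepatitis terms, hepatotoxicity, ...)
#' adapted from published DILI case definitions; it is a plain CSV the user
#' can edit, because the case definition is config, not code.
#'
#' @param path optional CSV with column `pt`.
#' @return character vector of PT names (lower case).
#' @export
dili_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dili_pt_lexicon.csv",
                                package = "faersignal", mustWork = TRUE)
  check_that(file.exists(path), paste0("file not found: ", path),
             "faersignal_io_error")
  lex <- readr::read_csv(path, col_types = "c", progress = FALSE)
  check_that(nrow(lex) > 0, "DILI lexicon is empty")
  normalize_name(lex$pt)
}

#' Consolidate liver-injury PTs into the unified DILI event
#'
#' Replaces every PT in a report's PT set that belongs to the lexicon with
#' the single event name `"DILI"`, then deduplicates the set, so a report
#' listing several liver PTs contributes exactly one DILI event. Applied
#' before drug filtering and counting. Idempotent; never increases the PT
#' set size.
#'
#' @param cases tibble from [assemble_cases()] (list-column `pts`).
#' @param lexicon character vector of PTs to consolidate, from
#'   [dili_lexicon()].
#' @param event_name the consolidated event label.
#' @return `cases` with the `pts` list-column rewritten.
#' @export
#' @examples
#' cases <- tibble::tibble(pts = list(c("alanine aminotransferase increased",
#'                                      "nausea")))
#' consolidate_dili(cases)$pts[[1]] # "DILI" "nausea"
consolidate_dili <- function(cases, lexicon = dili_lexicon(),
                             event_name = "DILI") {
  check_that(length(lexicon) > 0, "lexicon must be nonempty")
  lexicon <- normalize_name(lexicon)
  lens <- lengths(cases$pts)
  flat <- unlist(cases$pts, use.names = FALSE)
  hit <- normalize_name(flat) %in% lexicon
  if (!any(hit)) return(cases)
  flat[hit] <- event_name
  report <- rep.int(seq_along(lens), lens)
  affected <- unique(report[hit])
  sel <- report %in% affected
  rebuilt <- lapply(split(flat[sel], report[sel]), unique)
  cases$pts[sort(affected)] <- rebuilt
  cases
}

#' Default PT exclusion lists for top-k ranking
#'
#' Regular-expression lists applied only at the ranking stage: `death`
#' (death and fatality terms), `covid` (COVID-19 terms) and `malignancy`
#' (an editable list of neoplasm-progression terms). The malignancy list is
#' separate because ranking conventions differ on whether disease-progression
#' PTs belong in a toxicity table.
#'
#' @param path optional CSV with columns `list`, `pattern`.
#' @param include which named lists to activate.
#' @return named list of character pattern vectors.
#' @export
default_exclusions <- function(path = NULL,
                               include = c("death", "covid")) {
  path <- path %||% system.file("extdata", "exclusion_lists.csv",
                                package = "faersignal", mustWork = TRUE)
  check_that(file.exists(path), paste0("file not found: ", path),
             "faersignal_io_error")
  ex <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  ex <- ex[ex$list %in% include, , drop = FALSE]
  split(ex$pattern, ex$list)
}
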