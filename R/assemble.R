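# age unit divisors: value * factor = years
.age_factors <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                  DY = 1 / 365.25, HR = 1 / 8766)

.occp_labels <- c(MD = "Physician", PH = "Pharmacist", CN = "Consumer",
                  OT = "Other health professional",
                  HP = "Other health professional")

#' Assemble joined case reports from FAERS tables
#'
#' Joins the six tables on `primaryid` into one row per report: demographics
#' with age normalized to years (DEC x10, YR x1, MON /12, WK /52.1775,
#' DY /365.25, HR /8766), the PS-role drug plus the full verbatim drug list,
#' the PT set, the outcome-code set, the earliest therapy start date and the
#' event date. Reports with no REAC row are dropped (the analysis unit is a
#' report-event pair) and tallied; child rows whose `primaryid` is absent
#' from DEMO are tallied as orphans.
#'
#' @param tables a `faers_tables` list (from [generate_faers()] or
#'   [read_faers_dir()]), or a named list with at least `demo`, `drug`,
#'   `reac`.
#' @return a tibble of case reports, one row per `primaryid`, with
#'   list-columns `pts` (unique PT strings), `outcomes` (unique outcome
#'   codes) and `drugs` (verbatim drug names, named by role code); scalar
#'   columns `primaryid`, `caseid`, `fda_dt`, `event_dt`, `age_years`,
#'   `sex`, `country`, `reporter`, `ps_drug` (verbatim PS drug name),
#'   `start_dt`. The `tally` attribute records `no_reac_dropped` and
#'   `orphan_rows`.
#' @seealso [dedup_cases()], [add_canonical_drug()]
#' @export
assemble_cases <- function(tables) {
  demo <- as_tibble(tables$demo)
  drug <- as_tibble(tables$drug)
  reac <- as_tibble(tables$reac)
  outc <- as_tibble(tables$outc %||% tibble(primaryid = character()))
  ther <- as_tibble(tables$ther %||% tibble(primaryid = character()))
  check_that(nrow(demo) > 0, "DEMO table is empty", "faersignal_io_error")
  defaults <- list(caseid = NA_character_, fda_dt = NA_character_,
                   age = NA_real_, age_cod = NA_character_,
                   sex = NA_character_, reporter_country = NA_character_,
                   occp_cod = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(demo)) demo[[nm]] <- defaults[[nm]]
  }

  ids <- demo$primaryid
  orphans <- sum(!drug$primaryid %in% ids) + sum(!reac$primaryid %in% ids) +
    (if (nrow(outc)) sum(!outc$primaryid %in% ids) else 0L) +
    (if (nrow(ther)) sum(!ther$primaryid %in% ids) else 0L)

  split_col <- function(values, keys) {
    sp <- split(values, factor(keys, levels = unique(keys)))
    tibble(primaryid = names(sp), value = unname(sp))
  }

  reac2 <- reac %>%
    filter(!is.na(.data$pt), .data$primaryid %in% ids) %>%
    distinct(.data$primaryid, .data$pt)
  reac_g <- rename(split_col(reac2$pt, reac2$primaryid), pts = "value")

  drug2 <- filter(drug, .data$primaryid %in% ids)
  drug_g <- rename(
    split_col(setNames(drug2$drugname, drug2$role_cod), drug2$primaryid),
    drugs = "value")
  ps_g <- drug2 %>%
    filter(.data$role_cod == "PS") %>%
    distinct(.data$primaryid, .keep_all = TRUE) %>%
    select("primaryid", ps_drug = "drugname")

  outc_g <- if (nrow(outc) && "outc_cod" %in% names(outc)) {
    outc2 <- outc %>%
      filter(.data$primaryid %in% ids, !is.na(.data$outc_cod)) %>%
      distinct(.data$primaryid, .data$outc_cod)
    rename(split_col(outc2$outc_cod, outc2$primaryid), outcomes = "value")
  } else {
    tibble(primaryid = character(), outcomes = list())
  }

  ther_g <- if (nrow(ther) && "start_dt" %in% names(ther)) {
    ther %>%
      mutate(start_dt = parse_faers_date(.data$start_dt)) %>%
      filter(.data$primaryid %in% ids, !is.na(.data$start_dt)) %>%
      arrange(.data$primaryid, .data$start_dt) %>%
      distinct(.data$primaryid, .keep_all = TRUE) %>%
      select("primaryid", "start_dt")
  } else {
    tibble(primaryid = character(), start_dt = as.Date(character()))
  }

  age_f <- unname(.age_factors[demo$age_cod])
  cases <- demo %>%
    mutate(
      fda_dt = parse_faers_date(.data$fda_dt),
      event_dt = if ("event_dt" %in% names(demo))
        parse_faers_date(.data$event_dt) else as.Date(NA),
      age_years = .data$age * age_f,
      sex = if_else(.data$sex %in% c("F", "M"), .data$sex, "Unknown",
                    missing = "Unknown"),
      country = if_else(is.na(.data$reporter_country) | .data$reporter_country == "",
                        "Unknown", .data$reporter_country),
      reporter = dplyr::coalesce(unname(.occp_labels[.data$occp_cod]), "Unknown")
    ) %>%
    select(any_of(c("primaryid", "caseid", "fda_dt", "event_dt", "age_years",
                    "sex", "country", "reporter")))

  cases <- cases %>%
    left_join(reac_g, by = "primaryid") %>%
    left_join(drug_g, by = "primaryid") %>%
    left_join(ps_g, by = "primaryid") %>%
    left_join(outc_g, by = "primaryid") %>%
    left_join(ther_g, by = "primaryid")

  no_reac <- vapply(cases$pts, is.null, logical(1))
  dropped <- sum(no_reac)
  cases <- cases[!no_reac, , drop = FALSE]
  cases$outcomes <- lapply(cases$outcomes, function(x) x %||% character())

  attr(cases, "tally") <- list(no_reac_dropped = dropped, orphan_rows = orphans)
  cases
}
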