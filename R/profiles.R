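.country_groups <- c(US = "United States", JP = "Japan", CN = "China")

.outcome_severity <- c(DE = "Death", HO = "Hospitalization",
                       LT = "Life threatening", DS = "Disability",
                       OT = "Other serious", CA = "Other serious",
                       RI = "Other serious")

profile_block <- function(block, categories, counts, total) {
  tibble(block = block, category = categories,
         count = as.integer(counts),
         pct = if (total > 0) round2(100 * counts / total, 2) else 0)
}

drug_subset <- function(cases, drug) {
  cases[!is.na(cases$drug) & cases$drug == drug, , drop = FALSE]
}

#' Demographic profile for one drug
#'
#' Sex, reporter-country and reporter-occupation distributions (counts and
#' percentages to 2 dp) plus the age summary (mean and SD of normalized
#' years over non-missing values) for the primary-suspect reports of one
#' drug. Unknown categories absorb all missingness, so each block's counts
#' sum to the drug's report total.
#'
#' @param cases deduplicated case tibble with a canonical `drug` column.
#' @param drug canonical drug id.
#' @return tibble with columns `drug`, `block` (`sex`, `country`,
#'   `reporter`, `age`), `category`, `count`, `pct`, `value` (numeric, age
#'   rows only: mean, sd, n_missing; sd is 0 with a one-report subset).
#' @export
demographic_summary <- function(cases, drug) {
  sub <- drug_subset(cases, drug)
  check_that(nrow(sub) > 0, paste0("no reports for drug: ", drug),
             class = "faersignal_lookup_error")
  profile_demo_blocks(sub, drug)
}

profile_demo_blocks <- function(sub, drug) {
  total <- nrow(sub)
  sex_lv <- c("Female", "Male", "Unknown")
  sex <- factor(c(F = "Female", M = "Male", Unknown = "Unknown")[sub$sex],
                levels = sex_lv)
  country <- factor(
    dplyr::case_when(
      sub$country %in% names(.country_groups) ~
        .country_groups[sub$country],
      sub$country == "Unknown" ~ "Unknown",
      TRUE ~ "Other"),
    levels = c("United States", "Japan", "China", "Other", "Unknown"))
  rep_lv <- c("Physician", "Consumer", "Pharmacist",
              "Other health professional", "Unknown")
  reporter <- factor(sub$reporter, levels = rep_lv)

  ages <- sub$age_years[!is.na(sub$age_years)]
  age_rows <- tibble(
    block = "age",
    category = c("mean", "sd", "n_missing"),
    count = NA_integer_, pct = NA_real_,
    value = c(if (length(ages)) mean(ages) else NA_real_,
              if (length(ages) > 1) sd(ages) else if (length(ages) == 1) 0 else NA_real_,
              total - length(ages)))

  out <- bind_rows(
    profile_block("sex", sex_lv, tabulate(sex, length(sex_lv)), total),
    profile_block("country", levels(country),
                  tabulate(country, nlevels(country)), total),
    profile_block("reporter", rep_lv, tabulate(reporter, length(rep_lv)), total),
    age_rows)
  mutate(out, drug = drug, .before = 1)
}

#' Outcome distribution for one drug
#'
#' One outcome category per report by severity precedence
#' Death > Hospitalization > Life threatening > Disability > Other serious
#' (pooling OT, CA, RI) > Unknown (no outcome row), so a report with
#' several outcome codes counts once at its most severe.
#'
#' @inheritParams demographic_summary
#' @return tibble with columns `drug`, `block` (`outcome`), `category`,
#'   `count`, `pct`.
#' @export
outcome_distribution <- function(cases, drug) {
  sub <- drug_subset(cases, drug)
  check_that(nrow(sub) > 0, paste0("no reports for drug: ", drug),
             class = "faersignal_lookup_error")
  mutate(outcome_block(sub), drug = drug, .before = 1)
}

outcome_block <- function(sub) {
  lv <- c("Death", "Hospitalization", "Life threatening", "Disability",
          "Other serious", "Unknown")
  pick <- vapply(sub$outcomes, function(codes) {
    lab <- .outcome_severity[codes]
    lab <- lab[!is.na(lab)]
    if (!length(lab)) "Unknown" else lv[min(match(lab, lv))]
  }, character(1))
  f <- factor(pick, levels = lv)
  profile_block("outcome", lv, tabulate(f, length(lv)), nrow(sub))
}

#' Time-to-onset bins for one drug
#'
#' Onset is event date minus earliest therapy start date in days, binned
#' into the half-open intervals `[0, 7)`, `[7, 28)`, `[28, 60)`,
#' `[60, Inf)` (a 7-day onset falls in `7-28`); negative or missing onsets
#' are Unknown.
#'
#' @inheritParams demographic_summary
#' @return tibble with columns `drug`, `block` (`onset`), `category`,
#'   `count`, `pct`.
#' @export
onset_bins <- function(cases, drug) {
  sub <- drug_subset(cases, drug)
  check_that(nrow(sub) > 0, paste0("no reports for drug: ", drug),
             class = "faersignal_lookup_error")
  mutate(onset_block(sub), drug = drug, .before = 1)
}

onset_block <- function(sub) {
  lv <- c("0-7", "7-28", "28-60", ">=60", "Unknown")
  onset <- as.numeric(sub$event_dt - sub$start_dt)
  bin <- cut(onset, breaks = c(0, 7, 28, 60, Inf), labels = lv[1:4],
             right = FALSE)
  lab <- as.character(bin)
  lab[is.na(lab)] <- "Unknown"
  f <- factor(lab, levels = lv)
  profile_block("onset", lv, tabulate(f, length(lv)), nrow(sub))
}

#' Full cohort profile (demographics, outcomes, onset) for one drug
#'
#' @inheritParams demographic_summary
#' @return tibble stacking the [demographic_summary()],
#'   [outcome_distribution()] and [onset_bins()] blocks, preceded by a
#'   `total` row.
#' @export
cohort_profile <- function(cases, drug) {
  sub <- drug_subset(cases, drug)
  check_that(nrow(sub) > 0, paste0("no reports for drug: ", drug),
             class = "faersignal_lookup_error")
  bind_rows(
    tibble(drug = drug, block = "total", category = "total",
           count = nrow(sub), pct = NA_real_),
    profile_demo_blocks(sub, drug),
    mutate(outcome_block(sub), drug = drug, .before = 1),
    mutate(onset_block(sub), drug = drug, .before = 1))
}

#' Cohort profile of the DILI subset
#'
#' Same blocks as [cohort_profile()], restricted to reports whose PT set
#' contains the consolidated `"DILI"` event. A drug with zero DILI reports
#' yields an all-zero profile rather than an error.
#'
#' @inheritParams demographic_summary
#' @param event_name consolidated event label ([consolidate_dili()]).
#' @return tibble in the [cohort_profile()] layout; the `total` row counts
#'   DILI reports.
#' @export
dili_profile <- function(cases, drug, event_name = "DILI") {
  sub <- drug_subset(cases, drug)
  has_dili <- vapply(sub$pts, function(p) event_name %in% p, logical(1))
  sub <- sub[has_dili, , drop = FALSE]
  if (nrow(sub) == 0) {
    lv <- list(sex = c("Female", "Male", "Unknown"),
               outcome = c("Death", "Hospitalization", "Life threatening",
                           "Disability", "Other serious", "Unknown"),
               onset = c("0-7", "7-28", "28-60", ">=60", "Unknown"))
    empty <- bind_rows(lapply(names(lv), function(b) {
      profile_block(b, lv[[b]], rep(0L, length(lv[[b]])), 0)
    }))
    return(bind_rows(
      tibble(drug = drug, block = "total", category = "total",
             count = 0L, pct = NA_real_),
      mutate(empty, drug = drug, .before = 1)))
  }
  out <- bind_rows(
    tibble(drug = drug, block = "total", category = "total",
           count = nrow(sub), pct = NA_real_),
    profile_demo_blocks(sub, drug),
    mutate(outcome_block(sub), drug = drug, .before = 1),
    mutate(onset_block(sub), drug = drug, .before = 1))
  out
}
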