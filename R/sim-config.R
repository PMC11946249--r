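#' Simulation configuration for the synthetic report generator
#'
#' Defines the generative model behind [generate_faers()]: a spontaneous
#' reporting system in which each base case carries one primary-suspect (PS)
#' drug drawn from `drug_vocab` marginals, a set of MedDRA Preferred Terms
#' (PTs) drawn from `event_vocab` background probabilities tilted by any
#' injected `signals`, demographics with configurable missingness, therapy
#' and event dates, and a re-submission (duplicate) process.
#'
#' Injected signals act multiplicatively: conditional on PS drug `d`, PT
#' probabilities are `q_d(pt) = background(pt) * rrr(d, pt)`, renormalized
#' over the event vocabulary. A `reporting_rate_ratio` of 1 everywhere yields
#' exact drug-event independence.
#'
#' @param n_reports number of base cases (before duplication).
#' @param drug_vocab data frame with columns `drug` (canonical id), `prob`
#'   (marginal probability of being the PS drug) and `spellings` (list column
#'   of verbatim name spellings; defaults to the upper-cased id). Marginals
#'   must sum to at most 1; the remainder is assigned to background drugs
#'   outside the study set.
#' @param event_vocab data frame with columns `pt`, `prob` (background
#'   probability, summing to 1) and `soc`.
#' @param signals data frame with columns `drug`, `pt`, `rrr` (positive
#'   reporting-rate ratio), or `NULL` for the all-null model.
#' @param duplicate_rate probability in `[0, 1]` that a case is re-submitted
#'   under a new PRIMARYID with a strictly later FDA_DT.
#' @param missing_age_rate,missing_date_rate probabilities in `[0, 1]` of a
#'   missing age and missing therapy start date.
#' @param pts_per_report mean PTs per report; counts are shifted Poisson,
#'   `1 + Poisson(pts_per_report - 1)`, sampled without replacement.
#' @param concomitant_rate probability a case lists one concomitant
#'   (role `C`) background drug in addition to its PS drug.
#' @param onset_mean_days mean of the exponential therapy-start-to-event
#'   onset time, in days.
#' @param date_window character vector of two `YYYYMMDD` dates bounding
#'   FDA receipt dates.
#' @param seed integer seed making generation fully deterministic.
#' @return a `faers_sim_config` list, validated against the model invariants.
#' @seealso [generate_faers()], [expected_contingency()]
#' @export
#' @examples
#' cfg <- sim_config(
#'   n_reports = 1000,
#'   signals = data.frame(drug = "crizotinib", pt = "photopsia", rrr = 20),
#'   seed = 42
#' )
#' cfg$n_reports
sim_config <- function(n_reports,
                       drug_vocab = default_drug_vocab(),
                       event_vocab = default_event_vocab(),
                       signals = NULL,
                       duplicate_rate = 0.08,
                       missing_age_rate = 0.10,
                       missing_date_rate = 0.60,
                       pts_per_report = 1,
                       concomitant_rate = 0,
                       onset_mean_days = 30,
                       date_window = c("20110101", "20231231"),
                       seed = 1L) {
  drug_vocab <- as_tibble(drug_vocab)
  event_vocab <- as_tibble(event_vocab)
  if (!"spellings" %in% names(drug_vocab)) {
    drug_vocab$spellings <- lapply(drug_vocab$drug, toupper)
  }
  if (is.null(signals)) {
    signals <- tibble(drug = character(), pt = character(), rrr = numeric())
  }
  signals <- as_tibble(signals)

  cfg <- structure(
    list(
      n_reports = as.integer(n_reports),
      drug_vocab = drug_vocab, event_vocab = event_vocab, signals = signals,
      duplicate_rate = duplicate_rate,
      missing_age_rate = missing_age_rate,
      missing_date_rate = missing_date_rate,
      pts_per_report = pts_per_report,
      concomitant_rate = concomitant_rate,
      onset_mean_days = onset_mean_days,
      date_window = date_window,
      seed = as.integer(seed)
    ),
    class = "faers_sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config an object to validate.
#' @export
validate_sim_config <- function(config) {
  check_that(inherits(config, "faers_sim_config"),
             "`config` must be built by sim_config()")
  check_that(length(config$n_reports) == 1 && !is.na(config$n_reports) &&
               config$n_reports >= 1,
             "invariant violated: n_reports must be a positive integer")
  dv <- config$drug_vocab
  ev <- config$event_vocab
  check_that(all(c("drug", "prob") %in% names(dv)),
             "drug_vocab needs columns drug, prob")
  check_that(all(c("pt", "prob", "soc") %in% names(ev)),
             "event_vocab needs columns pt, prob, soc")
  check_that(all(dv$prob > 0) && sum(dv$prob) <= 1 + 1e-12,
             "invariant violated: drug marginal probabilities must be positive and sum to <= 1")
  check_that(all(ev$prob > 0) && abs(sum(ev$prob) - 1) < 1e-8,
             "invariant violated: event background probabilities must sum to 1")
  check_that(!anyDuplicated(dv$drug), "drug ids must be unique")
  check_that(!anyDuplicated(ev$pt), "event PTs must be unique")
  for (field in c("duplicate_rate", "missing_age_rate", "missing_date_rate",
                  "concomitant_rate")) {
    v <- config[[field]]
    check_that(length(v) == 1 && v >= 0 && v <= 1,
               paste0("invariant violated: ", field, " must lie in [0, 1]"))
  }
  check_that(config$pts_per_report >= 1,
             "invariant violated: pts_per_report must be >= 1")
  sg <- config$signals
  if (nrow(sg)) {
    check_that(all(sg$rrr > 0),
               "invariant violated: reporting_rate_ratio must be > 0")
    check_that(all(sg$drug %in% dv$drug),
               "signal references a drug absent from drug_vocab")
    check_that(all(sg$pt %in% ev$pt),
               "signal references a PT absent from event_vocab")
  }
  invisible(config)
}

#' Default study-drug vocabulary for simulations
#'
#' Five ALK tyrosine kinase inhibitors with generic and brand-name spellings
#' and marginal reporting probabilities roughly proportional to their
#' real-world report share (crizotinib the largest at 2%, the others
#' 0.8-1.3%), leaving ~94% of reports to background drugs.
#'
#' @return tibble with columns `drug`, `prob`, `spellings`.
#' @export
default_drug_vocab <- function() {
  tibble(
    drug = c("crizotinib", "ceritinib", "alectinib", "brigatinib", "lorlatinib"),
    prob = c(0.020, 0.009, 0.012, 0.008, 0.009),
    spellings = list(
      c("CRIZOTINIB", "XALKORI", "Crizotinib"),
      c("CERITINIB", "ZYKADIA"),
      c("ALECTINIB", "ALECENSA"),
      c("BRIGATINIB", "ALUNBRIG"),
      c("LORLATINIB", "LORBRENA", "LORVIQUA")
    )
  )
}

#' Default event vocabulary for simulations
#'
#' Thirty PTs spanning eight organ classes, including four liver-injury PTs
#' covered by the packaged DILI lexicon so hepatotoxicity consolidation can
#' be exercised end to end. Background probabilities sum to 1.
#'
#' @return tibble with columns `pt`, `prob`, `soc`.
#' @export
default_event_vocab <- function() {
  ev <- tibble(
    pt = c(
      "nausea", "vomiting", "diarrhea", "constipation", "decreased appetite",
      "alanine aminotransferase increased", "aspartate aminotransferase increased",
      "hepatic enzyme increased", "hepatic function abnormal",
      "photopsia", "visual impairment", "vitreous floaters",
      "hypercholesterolemia", "blood triglycerides increased", "hyperglycemia",
      "oedema peripheral", "pleural effusion", "pericardial effusion",
      "interstitial lung disease", "pneumonitis", "dyspnoea",
      "fatigue", "pyrexia", "headache", "dizziness",
      "rash", "pruritus", "anaemia", "bradycardia", "renal impairment"
    ),
    prob = c(
      0.060, 0.050, 0.055, 0.040, 0.030,
      0.020, 0.018, 0.015, 0.012,
      0.008, 0.020, 0.006,
      0.015, 0.010, 0.025,
      0.030, 0.025, 0.012,
      0.015, 0.018, 0.055,
      0.090, 0.050, 0.080, 0.060,
      0.065, 0.040, 0.040, 0.016, 0.030
    ),
    soc = c(
      rep("gastrointestinal disorders", 5),
      rep("hepatobiliary disorders", 4),
      rep("eye disorders", 3),
      rep("metabolism and nutrition disorders", 3),
      "general disorders and administration site conditions",
      "respiratory, thoracic and mediastinal disorders",
      "cardiac disorders",
      rep("respiratory, thoracic and mediastinal disorders", 3),
      rep("general disorders and administration site conditions", 2),
      rep("nervous system disorders", 2),
      rep("skin and subcutaneous tissue disorders", 2),
      "blood and lymphatic system disorders",
      "cardiac disorders",
      "renal and urinary disorders"
    )
  )
  ev$prob <- ev$prob / sum(ev$prob)
  ev
}
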