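#' Run the full signal-detection pipeline
#'
#' Orchestrates ingest, assembly, deduplication, DILI consolidation, drug
#' canonicalization, 2x2 contingency construction at PT and SOC level, the
#' four disproportionality algorithms, threshold flags, top-k ranking,
#' cross-drug overlap, cohort and DILI profiles, and the combined DILI
#' classification. The MGPS prior is fitted once on the pooled PT-level
#' tables of all study drugs (pass `prior` to override, e.g. with a prior
#' fitted on a full database).
#'
#' Outputs are deterministic given the input and configuration; when
#' `input` is a [sim_config()], the configuration's seed makes the whole
#' run reproducible. On any stage failure the partial files written to
#' `output_dir` are removed.
#'
#' @param input a directory of FAERS-format ASCII tables, a `faers_tables`
#'   list, or a [sim_config()] (simulated on the fly).
#' @param dict drug dictionary tibble or CSV path ([drug_dictionary()]).
#' @param hierarchy PT-to-SOC tibble or CSV path ([meddra_hierarchy()]).
#' @param lexicon DILI lexicon vector or CSV path ([dili_lexicon()]).
#' @param exclusions named list of exclusion patterns or CSV path
#'   ([default_exclusions()]).
#' @param drugs canonical drugs to analyze; default, every dictionary drug
#'   with at least one PS report.
#' @param top_k rows kept by the ranking stage.
#' @param bcpnn_mode,comparator passed to [disproportionality()].
#' @param prior optional pre-fitted [fit_mgps_prior()] object.
#' @param min_prior_tables minimum pooled tables required to fit the prior.
#' @param output_dir optional directory for the CSV/JSON artifact set.
#' @return an object of class `faers_run`: list with elements
#'   `pt_signals`, `soc_signals`, `top_signals`, `overlap`, `profiles`,
#'   `dili_profiles`, `dili_table`, `dili_assessment`, `prior`, `log`.
#' @export
run_faers_pipeline <- function(input,
                               dict = drug_dictionary(),
                               hierarchy = meddra_hierarchy(),
                               lexicon = dili_lexicon(),
                               exclusions = default_exclusions(),
                               drugs = NULL,
                               top_k = 30,
                               bcpnn_mode = c("paper_compat",
                                              "credible_interval"),
                               comparator = c("all", "other_study"),
                               prior = NULL,
                               min_prior_tables = 50,
                               output_dir = NULL) {
  bcpnn_mode <- match.arg(bcpnn_mode)
  comparator <- match.arg(comparator)

  # fail fast on configuration before any computation
  if (is.character(dict)) dict <- drug_dictionary(dict)
  if (is.character(hierarchy)) hierarchy <- meddra_hierarchy(hierarchy)
  if (is.character(lexicon) && length(lexicon) == 1 &&
      grepl("\\.csv$", lexicon)) {
    lexicon <- dili_lexicon(lexicon)
  }
  if (is.character(exclusions)) exclusions <- default_exclusions(exclusions)

  written <- character()
  out_file <- function(name) {
    path <- file.path(output_dir, name)
    written <<- c(written, path)
    path
  }

  run <- function() {
    # ingest
    if (inherits(input, "faers_sim_config")) {
      tables <- generate_faers(input)
    } else if (is.character(input)) {
      tables <- read_faers_dir(input)
    } else {
      tables <- input
    }
    ingest_rejects <- attr(tables, "rejects") %||% 0L

    cases <- assemble_cases(tables)
    tally <- attr(cases, "tally")
    cases <- dedup_cases(cases)
    dedup <- attr(cases, "dedup")
    cases <- consolidate_dili(cases, lexicon)
    cases <- add_canonical_drug(cases, dict)

    present <- unique(cases$drug[!is.na(cases$drug)])
    drugs <- drugs %||% intersect(unique(dict$drug), present)
    check_that(length(drugs) > 0, "no study-drug reports in the input",
               "faersignal_lookup_error")

    pt_tabs <- lapply(drugs, function(d) {
      contingency_all(cases, d, "PT", hierarchy, comparator = comparator)
    })
    names(pt_tabs) <- drugs
    if (is.null(prior)) {
      pooled <- bind_rows(pt_tabs)
      if (nrow(pooled) < min_prior_tables) {
        abort(paste0("stage mgps_prior: pooled table count ", nrow(pooled),
                     " below minimum ", min_prior_tables),
              class = "faersignal_fitting_error")
      }
      prior <- fit_mgps_prior(pooled)
    }

    finish <- function(tabs) {
      tabs %>%
        ror() %>%
        prr() %>%
        relative_reporting_ratio() %>%
        ebgm(prior) %>%
        bcpnn_ic(prior, mode = bcpnn_mode) %>%
        signal_flags()
    }

    pt_signals <- bind_rows(lapply(pt_tabs, finish))
    soc_signals <- bind_rows(lapply(drugs, function(d) {
      finish(contingency_all(cases, d, "SOC", hierarchy,
                             comparator = comparator))
    }))
    top_signals <- bind_rows(lapply(drugs, function(d) {
      top_k_signals(pt_signals[pt_signals$drug == d, , drop = FALSE],
                    exclusions, k = top_k)
    }))
    overlap <- signal_overlap(lapply(
      setNames(drugs, drugs),
      function(d) pt_signals$event[pt_signals$drug == d & pt_signals$signal]))
    profiles <- bind_rows(lapply(drugs, function(d) cohort_profile(cases, d)))
    dili_profiles <- bind_rows(lapply(drugs, function(d) dili_profile(cases, d)))
    dili_table <- pt_signals[pt_signals$event == "DILI", , drop = FALSE]
    dili_assessment <- if (nrow(dili_table)) {
      combined_dili_assessment(dili_table)
    } else {
      tibble(drug = character(), dili_associated = logical())
    }

    log <- list(
      ingested_reports = nrow(tables$demo),
      reject_rows = ingest_rejects,
      no_reac_dropped = tally$no_reac_dropped,
      orphan_rows = tally$orphan_rows,
      dedup_removed = dedup$removed_count,
      dedup_missing_fda_dt = dedup$missing_fda_dt,
      analyzed_reports = nrow(cases),
      drugs = drugs,
      bcpnn_mode = bcpnn_mode,
      comparator = comparator,
      prior = unclass(prior)[c("alpha1", "beta1", "alpha2", "beta2", "p",
                               "loglik", "n_tables")]
    )

    res <- structure(
      list(pt_signals = pt_signals, soc_signals = soc_signals,
           top_signals = top_signals, overlap = overlap,
           profiles = profiles, dili_profiles = dili_profiles,
           dili_table = dili_table, dili_assessment = dili_assessment,
           prior = prior, log = log),
      class = "faers_run")

    if (!is.null(output_dir)) {
      if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
      write_signal_table(pt_signals, out_file("pt_signals.csv"))
      write_signal_table(soc_signals, out_file("soc_signals.csv"))
      if (nrow(top_signals)) {
        write_signal_table(top_signals, out_file("top_signals.csv"))
      }
      if (nrow(dili_table)) {
        write_signal_table(dili_table, out_file("dili_table.csv"))
      }
      writeLines(readr::format_csv(select(overlap, -"events")),
                 out_file("overlap.csv"))
      write_profile_table(profiles, out_file("profiles.csv"))
      write_profile_table(dili_profiles, out_file("dili_profiles.csv"))
      writeLines(readr::format_csv(dili_assessment),
                 out_file("dili_assessment.csv"))
      jsonlite::write_json(log, out_file("run_log.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    res
  }

  tryCatch(run(), error = function(e) {
    unlink(written[file.exists(written)])
    abort(paste0("pipeline failed: ", conditionMessage(e)),
          class = "faersignal_pipeline_error", parent = e)
  })
}

#' @export
print.faers_run <- function(x, ...) {
  cat("FAERS signal-detection run\n")
  cat(sprintf("  reports analyzed: %d (of %d ingested; %d duplicates removed)\n",
              x$log$analyzed_reports, x$log$ingested_reports,
              x$log$dedup_removed))
  cat(sprintf("  drugs: %s\n", paste(x$log$drugs, collapse = ", ")))
  cat(sprintf("  PT-level pairs: %d (%d signalled) | SOC-level pairs: %d\n",
              nrow(x$pt_signals), sum(x$pt_signals$signal),
              nrow(x$soc_signals)))
  if (nrow(x$dili_assessment)) {
    assoc <- x$dili_assessment$drug[x$dili_assessment$dili_associated]
    cat(sprintf("  DILI-associated drugs: %s\n",
                if (length(assoc)) paste(assoc, collapse = ", ") else "none"))
  }
  invisible(x)
}
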