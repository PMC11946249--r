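#' Generate synthetic FAERS-format report tables
#'
#' Draws a multi-table spontaneous reporting dataset from the generative
#' model described in [sim_config()]: DEMO, DRUG, REAC, OUTC, INDI and THER
#' tables keyed by `primaryid`/`caseid`, with exactly one primary-suspect
#' drug per case, PT draws tilted by the injected signals, demographic
#' missingness, exponential time-to-onset, and duplicate re-submissions that
#' copy all child rows under a new PRIMARYID with a strictly later FDA_DT.
#'
#' Output is byte-stable for a fixed configuration (including seed).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `faers_tables`: a named list of tibbles
#'   (`demo`, `drug`, `reac`, `outc`, `indi`, `ther`) with a `manifest`
#'   attribute recording the ground truth (base case count, duplicate count,
#'   injected signals and their expected contingency cells).
#' @seealso [expected_contingency()], [write_faers_tables()], [assemble_cases()]
#' @export
#' @examples
#' tabs <- generate_faers(sim_config(n_reports = 200, seed = 7))
#' names(tabs)
#' nrow(tabs$demo)
generate_faers <- function(config) {
  validate_sim_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_reports
  dv <- config$drug_vocab
  ev <- config$event_vocab

  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  # --- PS drug assignment ------------------------------------------------
  p_other <- max(0, 1 - sum(dv$prob))
  drug_levels <- c(dv$drug, ".background")
  ps_drug <- sample(drug_levels, n, replace = TRUE, prob = c(dv$prob, p_other))

  background_names <- c(
    "OXALIPLATIN", "METFORMIN", "ASPIRIN", "IBUPROFEN", "ATORVASTATIN",
    "LISINOPRIL", "OMEPRAZOLE", "PEMBROLIZUMAB", "CARBOPLATIN", "PACLITAXEL"
  )
  verbatim <- character(n)
  for (i in seq_len(nrow(dv))) {
    idx <- which(ps_drug == dv$drug[i])
    sp <- dv$spellings[[i]]
    verbatim[idx] <- sp[sample.int(length(sp), length(idx), replace = TRUE)]
  }
  idx_bg <- which(ps_drug == ".background")
  verbatim[idx_bg] <- background_names[
    sample.int(length(background_names), length(idx_bg), replace = TRUE)]

  # --- PT draws: q_d(pt) proportional to background * rrr ----------------
  npts <- 1L + rpois(n, max(0, config$pts_per_report - 1))
  npts <- pmin(npts, nrow(ev))
  pt_of <- vector("list", n)
  for (d in drug_levels) {
    idx <- which(ps_drug == d)
    if (!length(idx)) next
    q <- conditional_pt_probs(config, d)
    one <- idx[npts[idx] == 1L]
    if (length(one)) {
      draws <- sample(ev$pt, length(one), replace = TRUE, prob = q)
      pt_of[one] <- as.list(draws)
    }
    multi <- idx[npts[idx] > 1L]
    for (i in multi) {
      pt_of[[i]] <- sample(ev$pt, npts[i], replace = FALSE, prob = q)
    }
  }

  # --- demographics ------------------------------------------------------
  age_years <- pmin(pmax(round(rnorm(n, 60, 15)), 18), 95)
  age_cod <- sample(c("YR", "MON", "DEC"), n, replace = TRUE,
                    prob = c(0.90, 0.06, 0.04))
  age_val <- ifelse(age_cod == "MON", age_years * 12,
                    ifelse(age_cod == "DEC", age_years / 10, age_years))
  age_missing <- runif(n) < config$missing_age_rate
  age_val[age_missing] <- NA_real_
  age_cod[age_missing] <- ""

  sex <- sample(c("F", "M", ""), n, replace = TRUE, prob = c(0.54, 0.39, 0.07))
  country <- sample(c("US", "JP", "CN", "FR", "DE", "GB", ""), n,
                    replace = TRUE, prob = c(0.50, 0.10, 0.04, 0.08, 0.08, 0.08, 0.12))
  occp <- sample(c("MD", "CN", "PH", "OT", "HP", ""), n, replace = TRUE,
                 prob = c(0.38, 0.30, 0.08, 0.12, 0.10, 0.02))

  # --- dates -------------------------------------------------------------
  win <- parse_faers_date(config$date_window)
  fda_dt <- win[1] + floor(runif(n) * as.numeric(win[2] - win[1] + 1))
  start_dt <- fda_dt - sample(30:400, n, replace = TRUE)
  onset <- round(rexp(n, rate = 1 / config$onset_mean_days))
  event_dt <- start_dt + onset
  end_dt <- start_dt + sample(30:200, n, replace = TRUE)
  date_missing <- runif(n) < config$missing_date_rate
  start_dt[date_missing] <- NA
  end_dt[date_missing] <- NA
  event_dt[date_missing] <- NA

  # --- outcomes ----------------------------------------------------------
  n_outc <- rbinom(n, 2, 0.35)
  outc_codes <- c("DE", "HO", "LT", "DS", "CA", "RI", "OT")
  outc_prob <- c(0.20, 0.30, 0.05, 0.03, 0.02, 0.05, 0.35)
  # vectorized draws; a clashing second code is dropped (sets are deduplicated
  # at assembly anyway)
  code1 <- sample(outc_codes, n, replace = TRUE, prob = outc_prob)
  code2 <- sample(outc_codes, n, replace = TRUE, prob = outc_prob)
  outc_pid <- c(primaryid[n_outc >= 1L],
                primaryid[n_outc == 2L & code1 != code2])
  outc_cid <- c(caseid[n_outc >= 1L],
                caseid[n_outc == 2L & code1 != code2])
  outc_cod <- c(code1[n_outc >= 1L],
                code2[n_outc == 2L & code1 != code2])

  demo <- tibble(
    primaryid = primaryid, caseid = caseid,
    fda_dt = format_faers_date(fda_dt),
    event_dt = format_faers_date(event_dt),
    age = age_val, age_cod = age_cod, sex = sex,
    reporter_country = country, occp_cod = occp
  )

  drug_tbl <- tibble(
    primaryid = primaryid, caseid = caseid, drug_seq = 1L,
    role_cod = "PS", drugname = verbatim
  )
  if (config$concomitant_rate > 0) {
    con_idx <- which(runif(n) < config$concomitant_rate)
    if (length(con_idx)) {
      drug_tbl <- bind_rows(drug_tbl, tibble(
        primaryid = primaryid[con_idx], caseid = caseid[con_idx],
        drug_seq = 2L, role_cod = "C",
        drugname = background_names[
          sample.int(length(background_names), length(con_idx), replace = TRUE)]
      ))
    }
  }

  reac <- tibble(
    primaryid = rep(primaryid, lengths(pt_of)),
    caseid = rep(caseid, lengths(pt_of)),
    pt = unlist(pt_of, use.names = FALSE)
  )
  outc <- tibble(primaryid = outc_pid, caseid = outc_cid, outc_cod = outc_cod)
  indi <- tibble(
    primaryid = primaryid, caseid = caseid, indi_drug_seq = 1L,
    indi_pt = ifelse(ps_drug == ".background", "neoplasm malignant",
                     "non-small cell lung cancer")
  )
  ther <- tibble(
    primaryid = primaryid, caseid = caseid, dsg_drug_seq = 1L,
    start_dt = format_faers_date(start_dt),
    end_dt = format_faers_date(end_dt)
  )

  # --- duplicate re-submissions -----------------------------------------
  dup_idx <- which(runif(n) < config$duplicate_rate)
  if (length(dup_idx)) {
    new_pid <- paste0(caseid[dup_idx], "2")
    new_fda <- format_faers_date(fda_dt[dup_idx] + sample(10:200, length(dup_idx),
                                                          replace = TRUE))
    redo <- function(tbl) {
      child <- tbl[tbl$primaryid %in% primaryid[dup_idx], , drop = FALSE]
      key <- setNames(new_pid, primaryid[dup_idx])
      child$primaryid <- unname(key[child$primaryid])
      bind_rows(tbl, child)
    }
    demo_dup <- demo[dup_idx, ]
    demo_dup$primaryid <- new_pid
    demo_dup$fda_dt <- new_fda
    demo <- bind_rows(demo, demo_dup)
    drug_tbl <- redo(drug_tbl)
    reac <- redo(reac)
    outc <- redo(outc)
    indi <- redo(indi)
    ther <- redo(ther)
  }

  manifest <- list(
    n_reports = n,
    n_cases = n,
    n_primaryids = n + length(dup_idx),
    n_duplicates = length(dup_idx),
    signals = config$signals,
    seed = config$seed
  )
  if (nrow(config$signals)) {
    manifest$expected_cells <- purrr::pmap_dfr(
      config$signals[, c("drug", "pt")],
      function(drug, pt) {
        ec <- expected_contingency(config, drug, pt)
        tibble(drug = drug, pt = pt, a = ec$a, b = ec$b, c = ec$c, d = ec$d)
      }
    )
  }

  structure(
    list(demo = demo, drug = drug_tbl, reac = reac, outc = outc,
         indi = indi, ther = ther),
    manifest = manifest,
    class = c("faers_tables", "list")
  )
}

# conditional PT distribution for a PS drug: background tilted by rrr and
# renormalized; ".background" and unsignalled drugs use the background as-is
conditional_pt_probs <- function(config, drug) {
  ev <- config$event_vocab
  q <- ev$prob
  sg <- config$signals
  if (nrow(sg)) {
    rows <- sg[sg$drug == drug, , drop = FALSE]
    if (nrow(rows)) {
      m <- match(rows$pt, ev$pt)
      q[m] <- q[m] * rows$rrr
      q <- q / sum(q)
    }
  }
  q
}

#' Exact expected contingency cells under the generative model
#'
#' Computes, with no sampling, the expected `(a, b, c, d)` cell values of
#' the deduplicated report-level 2x2 table for one drug-event pair under a
#' [sim_config()]. With one PT per report the event-inclusion probability is
#' exactly the renormalized tilted background `q_d(pt)`; with `k > 1` PTs
#' the inclusion probability uses the independent-draw form
#' `1 - (1 - q) * exp(-(mean - 1) * q)`, exact for draws with replacement and
#' a close upper-tail approximation for the without-replacement sampler.
#' Tests that need an exact oracle use one-PT configurations.
#'
#' @param config a [sim_config()] object.
#' @param drug canonical drug id present in the configuration's vocabulary.
#' @param pt PT name present in the event vocabulary.
#' @return one-row tibble with real-valued columns `a`, `b`, `c`, `d`,
#'   `n`, `expected` (`E = (a+b)(a+c)/N`).
#' @export
#' @examples
#' cfg <- sim_config(
#'   n_reports = 100000,
#'   drug_vocab = data.frame(drug = "X", prob = 0.01),
#'   event_vocab = data.frame(pt = c("Y", "other"), prob = c(0.02, 0.98),
#'                            soc = "general disorders"),
#'   signals = data.frame(drug = "X", pt = "Y", rrr = 5)
#' )
#' expected_contingency(cfg, "X", "Y")$a # ~92.6
expected_contingency <- function(config, drug, pt) {
  validate_sim_config(config)
  dv <- config$drug_vocab
  ev <- config$event_vocab
  if (!drug %in% dv$drug) {
    abort(paste0("unknown drug: ", drug), class = "faersignal_lookup_error")
  }
  if (!pt %in% ev$pt) {
    abort(paste0("unknown PT: ", pt), class = "faersignal_lookup_error")
  }
  n <- config$n_reports
  m <- config$pts_per_report
  pt_i <- match(pt, ev$pt)

  incl <- function(d) {
    q <- conditional_pt_probs(config, d)[pt_i]
    if (m == 1) q else 1 - (1 - q) * exp(-(m - 1) * q)
  }

  p_other <- max(0, 1 - sum(dv$prob))
  p_drug <- setNames(dv$prob, dv$drug)

  a <- n * p_drug[[drug]] * incl(drug)
  b <- n * p_drug[[drug]] - a
  c_cell <- sum(vapply(setdiff(dv$drug, drug), function(d) {
    n * p_drug[[d]] * incl(d)
  }, numeric(1))) + n * p_other * incl(".background")
  d_cell <- n - a - b - c_cell
  ab <- a + b; ac <- a + c_cell
  tibble(a = a, b = b, c = c_cell, d = d_cell, n = n,
         expected = ab * ac / n)
}

#' Write FAERS-format ASCII tables to a directory
#'
#' Writes the six "$"-delimited text files (`DEMO.txt`, `DRUG.txt`,
#' `REAC.txt`, `OUTC.txt`, `INDI.txt`, `THER.txt`) plus, when the tables
#' carry a generator manifest, a `manifest.json` ground-truth record.
#'
#' @param tables a `faers_tables` object (or named list of data frames).
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of file paths written.
#' @export
write_faers_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in c("demo", "drug", "reac", "outc", "indi", "ther")) {
    tbl <- tables[[nm]]
    if (is.null(tbl)) next
    path <- file.path(dir, paste0(toupper(nm), ".txt"))
    out <- as.data.frame(tbl)
    for (j in seq_along(out)) {
      v <- out[[j]]
      if (is.numeric(v)) v <- ifelse(is.na(v), "", format(v, trim = TRUE, scientific = FALSE))
      v[is.na(v)] <- ""
      out[[j]] <- as.character(v)
    }
    con <- file(path, open = "wb")
    writeLines(c(paste(toupper(names(out)), collapse = "$"),
                 do.call(paste, c(out, sep = "$"))), con)
    close(con)
    paths <- c(paths, path)
  }
  manifest <- attr(tables, "manifest")
  if (!is.null(manifest)) {
    mpath <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    paths <- c(paths, mpath)
  }
  invisible(paths)
}
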