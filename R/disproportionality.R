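#' Reporting odds ratio with Wald 95% CI
#'
#' `ROR = ad / bc`, with the 95% Wald interval
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. No continuity
#' correction is applied: any zero cell leaves the statistic undefined
#' (`ror_defined = FALSE`), which the minimum-count signal rule makes
#' largely moot.
#'
#' @param tables a contingency tibble with integer columns `a`, `b`, `c`,
#'   `d` (e.g. from [contingency_all()]); extra columns pass through.
#' @return `tables` with columns `ror`, `ror_low`, `ror_high`,
#'   `ror_defined` appended.
#' @export
#' @examples
#' ror(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
ror <- function(tables) {
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c_ <- as.numeric(tables$c); d <- as.numeric(tables$d)
  defined <- a > 0 & b > 0 & c_ > 0 & d > 0
  est <- ifelse(defined, (a * d) / (b * c_), NA_real_)
  se <- ifelse(defined, sqrt(1 / a + 1 / b + 1 / c_ + 1 / d), NA_real_)
  mutate(tables,
         ror = est,
         ror_low = exp(log(est) - 1.96 * se),
         ror_high = exp(log(est) + 1.96 * se),
         ror_defined = defined)
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' `PRR = [a / (a+b)] / [c / (c+d)]` and the Pearson chi-squared statistic
#' without continuity correction,
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`. Undefined when the drug margin
#' or the background event count is zero. A Yates-corrected chi-squared is
#' available for sensitivity analyses.
#'
#' @inheritParams ror
#' @param yates apply the Yates continuity correction to chi-squared.
#' @return `tables` with `prr`, `chi2`, `prr_defined` appended.
#' @export
#' @examples
#' prr(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
prr <- function(tables, yates = FALSE) {
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c_ <- as.numeric(tables$c); d <- as.numeric(tables$d)
  n <- a + b + c_ + d
  defined <- (a + b) > 0 & c_ > 0 & (c_ + d) > 0
  est <- ifelse(defined, (a / (a + b)) / (c_ / (c_ + d)), NA_real_)
  dev <- abs(a * d - b * c_)
  if (yates) dev <- pmax(dev - n / 2, 0)
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- ifelse(denom > 0, n * dev^2 / denom, NA_real_)
  mutate(tables, prr = est, chi2 = chi2, prr_defined = defined)
}

#' Relative reporting ratio (observed / expected)
#'
#' The raw observed-to-expected ratio `a / E` with
#' `E = (a+b)(a+c) / N` — the quantity the Bayesian methods shrink.
#'
#' @inheritParams ror
#' @return `tables` with `obs_exp` appended (`NA` when `E = 0`).
#' @export
relative_reporting_ratio <- function(tables) {
  e <- (tables$a + tables$b) * (tables$a + tables$c) /
    (tables$a + tables$b + tables$c + tables$d)
  mutate(tables, obs_exp = ifelse(e > 0, tables$a / e, NA_real_))
}

#' Threshold-based signal classification
#'
#' Applies the standard per-algorithm signal criteria and their
#' conjunction:
#' * ROR: `a >= 3` and lower 95% CI bound `> 1`;
#' * PRR: `a >= 3`, `PRR >= 2` and `chi2 >= 4`;
#' * BCPNN: `IC025 > 0`;
#' * MGPS: `EBGM05 > 2`;
#' * `signal`: all four (the combined classification, trading the
#'   frequentist methods' sensitivity against Bayesian shrinkage's
#'   specificity).
#'
#' @param results a tibble carrying `a`, `ror_low`, `ror_defined`, `prr`,
#'   `chi2`, `prr_defined`, `ic025`, `ebgm05` (from the statistic
#'   functions or [disproportionality()]).
#' @param min_a minimum report count for the frequentist criteria.
#' @param ror_low_gt,prr_min,chi2_min,ic025_gt,ebgm05_gt threshold values.
#' @return `results` with logical columns `ror_flag`, `prr_flag`,
#'   `bcpnn_flag`, `mgps_flag`, `signal` appended.
#' @export
signal_flags <- function(results, min_a = 3, ror_low_gt = 1, prr_min = 2,
                         chi2_min = 4, ic025_gt = 0, ebgm05_gt = 2) {
  results <- mutate(
    results,
    ror_flag = .data$a >= min_a & .data$ror_defined &
      !is.na(.data$ror_low) & .data$ror_low > ror_low_gt,
    prr_flag = .data$a >= min_a & .data$prr_defined &
      !is.na(.data$prr) & .data$prr >= prr_min &
      !is.na(.data$chi2) & .data$chi2 >= chi2_min,
    bcpnn_flag = !is.na(.data$ic025) & .data$ic025 > ic025_gt,
    mgps_flag = !is.na(.data$ebgm05) & .data$ebgm05 > ebgm05_gt
  )
  mutate(results,
         signal = .data$ror_flag & .data$prr_flag &
           .data$bcpnn_flag & .data$mgps_flag)
}

#' Four-algorithm disproportionality analysis for one drug
#'
#' The main per-drug analysis: builds every 2x2 table at the requested
#' level, computes ROR, PRR/chi-squared, BCPNN IC and MGPS EBGM, and
#' applies the signal thresholds. The MGPS prior is fitted on this drug's
#' full table set unless a pre-fitted prior (e.g. one fitted on the whole
#' database) is supplied.
#'
#' @inheritParams contingency_all
#' @param prior a [fit_mgps_prior()] object, or `NULL` to fit on the
#'   drug's own tables.
#' @param bcpnn_mode see [bcpnn_ic()].
#' @param ... threshold overrides passed to [signal_flags()].
#' @return tibble with one row per event: contingency cells, all four
#'   statistics with intervals, per-algorithm flags and the combined
#'   `signal` flag.
#' @export
disproportionality <- function(cases, drug, level = c("PT", "SOC"),
                               hierarchy = meddra_hierarchy(),
                               comparator = c("all", "other_study"),
                               prior = NULL,
                               bcpnn_mode = c("paper_compat",
                                              "credible_interval"),
                               ...) {
  level <- match.arg(level)
  bcpnn_mode <- match.arg(bcpnn_mode)
  tabs <- contingency_all(cases, drug, level, hierarchy,
                          comparator = match.arg(comparator))
  if (is.null(prior)) prior <- fit_mgps_prior(tabs)
  tabs %>%
    ror() %>%
    prr() %>%
    relative_reporting_ratio() %>%
    ebgm(prior) %>%
    bcpnn_ic(prior, mode = bcpnn_mode) %>%
    signal_flags(...)
}
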