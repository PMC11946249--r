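tbl1 <- tibble::tibble(a = 10, b = 90, c = 100, d = 9900)

test_that("ROR with Wald CI matches the direct formula", {
  r <- ror(tbl1)
  expect_equal(r$ror, 11, tolerance = 1e-12)
  expect_equal(round2(r$ror_low), 5.56)
  # exp(ln 11 + 1.96 * 0.348155...) = 21.7645
  expect_equal(round2(r$ror_high), 21.76)
  expect_true(r$ror_defined)
  # odds equality
  expect_equal(ror(tibble::tibble(a = 5, b = 5, c = 50, d = 50))$ror, 1)
  # zero cell: undefined, no silent continuity correction
  z <- ror(tibble::tibble(a = 0, b = 10, c = 10, d = 100))
  expect_false(z$ror_defined)
  expect_true(is.na(z$ror))
})

test_that("PRR and Pearson chi-squared match the direct formulas", {
  p <- prr(tbl1)
  expect_equal(p$prr, 10, tolerance = 1e-12)
  expect_equal(round2(p$chi2), 74.45)
  exact <- prr(tibble::tibble(a = 5, b = 45, c = 50, d = 450))
  expect_equal(exact$prr, 1, tolerance = 1e-12)
  expect_equal(exact$chi2, 0, tolerance = 1e-12)
  z <- prr(tibble::tibble(a = 10, b = 90, c = 0, d = 9900))
  expect_false(z$prr_defined)
})

test_that("observed/expected ratio matches arithmetic", {
  r <- relative_reporting_ratio(tbl1)
  expect_equal(round2(r$obs_exp), 9.18)
  expect_equal(relative_reporting_ratio(
    tibble::tibble(a = 5, b = 45, c = 50, d = 450))$obs_exp, 1)
  expect_equal(relative_reporting_ratio(
    tibble::tibble(a = 0, b = 45, c = 50, d = 450))$obs_exp, 0)
})

test_that("frequentist statistics agree with a brute-force oracle", {
  tabs <- random_tables(1000, seed = 99)
  got <- relative_reporting_ratio(prr(ror(tabs)))
  for (i in c(1, 250, 777)) { # spot-readable; full vector checked below
    expect_true(got$ror_defined[i])
  }
  a <- as.numeric(tabs$a); b <- as.numeric(tabs$b)
  c_ <- as.numeric(tabs$c); d <- as.numeric(tabs$d); n <- as.numeric(tabs$n)
  expect_lt(max(abs(got$ror - (a * d) / (b * c_)) / got$ror), 1e-12)
  expect_lt(max(abs(got$prr - (a / (a + b)) / (c_ / (c_ + d))) / got$prr),
            1e-12)
  chi_oracle <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_lt(max(abs(got$chi2 - chi_oracle) / pmax(chi_oracle, 1)), 1e-12)
  expect_lt(max(abs(got$obs_exp - a / ((a + b) * (a + c_) / n)) /
                  got$obs_exp), 1e-12)
  # ROR >= PRR for positively associated tables
  pos <- a * d > b * c_
  expect_true(all(got$ror[pos] >= got$prr[pos]))
})

test_that("conjugate posterior matches the closed gamma form", {
  prior <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1,
                          p = 0.5), class = "mgps_prior")
  t <- tibble::tibble(a = 10, expected = 1.0891)
  got <- ebgm(t, prior)
  # posterior is Gamma(11, 2.0891): EBGM = exp(digamma(11) - log(2.0891))
  expect_equal(got$ebgm, exp(digamma(11) - log(2.0891)), tolerance = 1e-10)
  expect_equal(round2(got$ebgm), 5.03)
  # 5th percentile via the chi-squared quantile identity
  expect_equal(got$ebgm05, qchisq(0.05, df = 22) / 2 / 2.0891,
               tolerance = 1e-7)
  expect_equal(round2(got$ebgm05), 2.95)
})

test_that("a mixture of equal components degenerates to one component", {
  eq <- structure(list(alpha1 = 2, beta1 = 3, alpha2 = 2, beta2 = 3, p = 0.3),
                  class = "mgps_prior")
  one <- structure(list(alpha1 = 2, beta1 = 3, alpha2 = 2, beta2 = 3, p = 1 - 1e-15),
                   class = "mgps_prior")
  t <- tibble::tibble(a = c(4, 40), expected = c(2, 11))
  expect_equal(ebgm(t, eq)$ebgm, ebgm(t, one)$ebgm, tolerance = 1e-12)
  expect_equal(ebgm(t, eq)$ebgm05, ebgm(t, one)$ebgm05, tolerance = 1e-8)
})

test_that("EBGM and EBGM05 agree with numerical posterior integration", {
  set.seed(7)
  n <- 100
  priors <- replicate(n, structure(list(
    alpha1 = runif(1, 0.2, 3), beta1 = runif(1, 0.2, 3),
    alpha2 = runif(1, 0.5, 5), beta2 = runif(1, 0.5, 5),
    p = runif(1, 0.1, 0.9)), class = "mgps_prior"), simplify = FALSE)
  as <- sample(1:120, n, replace = TRUE)
  es <- runif(n, 0.5, 60)
  max_err <- 0
  for (i in seq_len(n)) {
    got <- ebgm(tibble::tibble(a = as[i], expected = es[i]), priors[[i]])
    want <- oracle_ebgm(as[i], es[i], priors[[i]])
    max_err <- max(max_err,
                   abs(got$ebgm - want[["ebgm"]]),
                   abs(got$ebgm05 - want[["ebgm05"]]))
  }
  expect_lt(max_err, 1e-6)
})

test_that("EBGM shrinks between prior geometric mean and observed ratio", {
  prior <- structure(list(alpha1 = 0.7, beta1 = 0.9, alpha2 = 2, beta2 = 2,
                          p = 0.4), class = "mgps_prior")
  prior_gm <- exp(prior$p * (digamma(prior$alpha1) - log(prior$beta1)) +
                    (1 - prior$p) * (digamma(prior$alpha2) - log(prior$beta2)))
  set.seed(11)
  for (i in 1:100) {
    a <- sample(1:200, 1); e <- runif(1, 0.5, 40)
    g <- ebgm(tibble::tibble(a = a, expected = e), prior)$ebgm
    lo <- min(prior_gm, a / e); hi <- max(prior_gm, a / e)
    expect_gt(g, lo - 1e-9)
    expect_lt(g, hi + 1e-9)
  }
})

test_that("EBGM is nondecreasing in a for fixed E and prior", {
  prior <- structure(list(alpha1 = 0.5, beta1 = 0.5, alpha2 = 3, beta2 = 3,
                          p = 0.35), class = "mgps_prior")
  g <- ebgm(tibble::tibble(a = 0:80, expected = 9.5), prior)$ebgm
  expect_true(all(diff(g) > -1e-10))
})

test_that("prior fitting recovers an all-null database mean near 1", {
  set.seed(23)
  e <- exp(rnorm(600, 1, 1.2))
  tabs <- tibble::tibble(a = rpois(600, e), expected = e)
  prior <- fit_mgps_prior(tabs)
  expect_true(prior$converged)
  expect_equal(mgps_prior_mean(prior), 1, tolerance = 0.1)
})

test_that("fitted likelihood dominates the truth on 2-gamma mixture data", {
  set.seed(29)
  truth <- list(alpha1 = 0.8, beta1 = 0.8, alpha2 = 6, beta2 = 2, p = 0.7)
  n <- 800
  comp <- rbinom(n, 1, truth$p)
  lam <- ifelse(comp == 1, rgamma(n, truth$alpha1, truth$beta1),
                rgamma(n, truth$alpha2, truth$beta2))
  e <- exp(rnorm(n, 0.5, 1))
  tabs <- tibble::tibble(a = rpois(n, lam * e), expected = e)
  prior <- fit_mgps_prior(tabs)
  ll <- function(th) {
    f1 <- dnbinom(tabs$a, size = th$alpha1, prob = th$beta1 / (th$beta1 + e))
    f2 <- dnbinom(tabs$a, size = th$alpha2, prob = th$beta2 / (th$beta2 + e))
    sum(log(th$p * f1 + (1 - th$p) * f2))
  }
  expect_gte(prior$loglik, ll(truth) - 0.1)
})

test_that("prior fitting demands at least 50 usable tables", {
  tabs <- tibble::tibble(a = rep(1, 49), expected = rep(1, 49))
  expect_error(fit_mgps_prior(tabs), class = "faersignal_fitting_error")
})

test_that("tidy and glance expose the prior fit", {
  set.seed(31)
  e <- exp(rnorm(200, 1, 1))
  prior <- fit_mgps_prior(tibble::tibble(a = rpois(200, e), expected = e))
  td <- tidy(prior)
  expect_equal(td$term, c("alpha1", "beta1", "alpha2", "beta2", "p"))
  expect_true(all(td$estimate > 0))
  gl <- glance(prior)
  expect_named(gl, c("logLik", "n_tables", "prior_mean", "converged"))
  expect_equal(gl$n_tables, 200)
  expect_output(print(prior), "gamma-mixture")
})

test_that("paper-compat IC is log2 EBGM with a constant IC025 offset", {
  prior <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1,
                          p = 0.5), class = "mgps_prior")
  t <- tibble::tibble(a = c(10, 40), expected = c(1.0891, 40))
  got <- bcpnn_ic(t, prior, mode = "paper_compat")
  expect_equal(got$ic, log2(got$ebgm), tolerance = 1e-12)
  expect_equal(got$ic - got$ic025, c(1.66, 1.66), tolerance = 1e-12)
  # independence with a flat-ish prior: IC near 0
  expect_lt(abs(got$ic[2]), 0.1)
})

test_that("credible-interval IC025 is the posterior 2.5th percentile", {
  prior <- structure(list(alpha1 = 1.2, beta1 = 0.8, alpha2 = 3, beta2 = 2.5,
                          p = 0.4), class = "mgps_prior")
  t <- tibble::tibble(a = 25, expected = 6)
  got <- bcpnn_ic(t, prior, mode = "credible_interval")
  want <- oracle_posterior(25, 6, prior)$quantile(0.025)
  expect_equal(got$ic025, log2(want), tolerance = 1e-6)
  expect_lt(got$ic025, got$ic)
})

test_that("signal thresholds reproduce the published starring pattern", {
  ref <- alk_dili_reference()
  flags <- ref |>
    dplyr::mutate(a = dili_reports, ror_defined = TRUE, prr_defined = TRUE) |>
    signal_flags()
  # brigatinib: three algorithms fire but BCPNN does not
  brig <- flags[flags$drug == "brigatinib", ]
  expect_true(brig$ror_flag && brig$prr_flag && brig$mgps_flag)
  expect_false(brig$bcpnn_flag)
  expect_false(brig$signal)
  # combined classification: exactly the three hepatotoxicity-associated drugs
  expect_setequal(flags$drug[flags$signal],
                  c("crizotinib", "ceritinib", "alectinib"))
  # an EBGM05 of 1.88 sits below the MGPS threshold
  soc <- alk_signal_reference() |>
    dplyr::mutate(a = n, ror_defined = TRUE, prr_defined = TRUE) |>
    signal_flags()
  cer_met <- soc[soc$drug == "ceritinib" &
                   soc$event == "metabolism and nutrition disorders", ]
  expect_false(cer_met$mgps_flag)
  expect_true(cer_met$ror_flag)
  # minimum-count rule overrides huge statistics
  tiny <- signal_flags(tibble::tibble(
    a = 2, ror_low = 50, ror_defined = TRUE, prr = 100, chi2 = 500,
    prr_defined = TRUE, ic025 = 3, ebgm05 = 40))
  expect_false(tiny$ror_flag)
  expect_false(tiny$prr_flag)
  expect_true(tiny$bcpnn_flag && tiny$mgps_flag)
  expect_false(tiny$signal)
})

test_that("top-k ranking excludes, filters, sorts and truncates", {
  res <- tibble::tibble(
    drug = "d", level = "PT",
    event = c("death", "pe", "pf", "pg", "ph"),
    a = c(9, 7, 7, 3, 1),
    ebgm = c(2, 5, 9, 2, 2),
    ror_flag = TRUE, prr_flag = TRUE, bcpnn_flag = TRUE, mgps_flag = TRUE,
    signal = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  top <- top_k_signals(res, k = 3)
  # the excluded death row promotes the a=7 pair; EBGM breaks the tie
  expect_equal(top$event, c("pf", "pe", "pg"))
  expect_equal(top_k_signals(res, k = 100)$event, c("pf", "pe", "pg"))
  any_rule <- top_k_signals(res, k = 5, rule = "any")
  expect_true("ph" %in% any_rule$event)
  expect_error(top_k_signals(res, k = 0),
               class = "faersignal_argument_error")
})

test_that("signal overlap counts exact subsets and conserves the union", {
  ov <- signal_overlap(list(A = c("x", "y"), B = c("y", "z")))
  get <- function(s) ov$count[ov$drugs == s]
  expect_equal(get("A"), 1)
  expect_equal(get("B"), 1)
  expect_equal(get("A&B"), 1)
  expect_equal(sum(ov$count), 3)

  sets <- replicate(5, c("DILI", "nausea"), simplify = FALSE)
  names(sets) <- study_drugs
  ov5 <- signal_overlap(sets)
  five_way <- ov5[ov5$n_drugs == 5, ]
  expect_equal(five_way$count, 2)
  expect_true("DILI" %in% five_way$events[[1]])
  expect_equal(sum(ov5$count), 2)
})

test_that("combined DILI assessment reflects the conjunction flag", {
  res <- tibble::tibble(drug = c("a", "b"), signal = c(TRUE, FALSE))
  out <- combined_dili_assessment(res)
  expect_equal(out$dili_associated, c(TRUE, FALSE))
})
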