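profile_fixture <- function() {
  tibble::tibble(
    primaryid = as.character(1:6), caseid = as.character(1:6),
    fda_dt = as.Date("2022-06-01"),
    drug = c(rep("crizotinib", 5), "ceritinib"),
    age_years = c(50, 60, NA, 70, 40, 55),
    sex = c("F", "F", "M", "Unknown", "F", "M"),
    country = c("US", "US", "JP", "Unknown", "FR", "CN"),
    reporter = c("Physician", "Consumer", "Physician", "Unknown",
                 "Pharmacist", "Physician"),
    outcomes = list(c("HO", "DE"), "HO", character(), c("CA", "RI"), "LT",
                    "DE"),
    pts = list(c("DILI", "nausea"), "nausea", "rash", "DILI", "rash",
               "nausea"),
    event_dt = as.Date(c("2022-01-10", "2022-01-08", NA, "2022-03-01",
                         "2021-12-31", NA)),
    start_dt = as.Date(c("2022-01-05", "2022-01-01", NA, "2022-01-01",
                         "2022-01-01", NA)))
}

test_that("demographic blocks count, percent and absorb missingness", {
  prof <- demographic_summary(profile_fixture(), "crizotinib")
  sex <- prof[prof$block == "sex", ]
  expect_equal(sum(sex$count), 5)
  expect_equal(sex$count[sex$category == "Female"], 3L)
  expect_equal(sex$pct[sex$category == "Female"], 60)
  expect_equal(sum(sex$pct), 100)
  age <- prof[prof$block == "age", ]
  expect_equal(age$value[age$category == "mean"], mean(c(50, 60, 70, 40)))
  expect_equal(age$value[age$category == "n_missing"], 1)
  country <- prof[prof$block == "country", ]
  expect_equal(country$count[country$category == "United States"], 2L)
  expect_equal(country$count[country$category == "Other"], 1L)
  expect_error(demographic_summary(profile_fixture(), "lorlatinib"),
               class = "faersignal_lookup_error")
})

test_that("age summary handles the degenerate subsets", {
  cases <- profile_fixture()[4, ]
  cases$age_years <- 50
  prof <- demographic_summary(cases, "crizotinib")
  age <- prof[prof$block == "age", ]
  expect_equal(age$value[age$category == "mean"], 50)
  expect_equal(age$value[age$category == "sd"], 0) # single report: flagged 0
  cases$age_years <- NA_real_
  prof2 <- demographic_summary(cases, "crizotinib")
  expect_true(is.na(prof2$value[prof2$block == "age" &
                                  prof2$category == "mean"]))
})

test_that("outcome precedence picks the most severe code per report", {
  out <- outcome_distribution(profile_fixture(), "crizotinib")
  expect_equal(out$count[out$category == "Death"], 1L) # {HO, DE} -> Death
  expect_equal(out$count[out$category == "Hospitalization"], 1L)
  expect_equal(out$count[out$category == "Other serious"], 1L) # {CA, RI}
  expect_equal(out$count[out$category == "Life threatening"], 1L)
  expect_equal(out$count[out$category == "Unknown"], 1L) # no OUTC row
  expect_equal(sum(out$count), 5)
  expect_equal(sum(out$pct), 100)
})

test_that("onset bins are half-open with boundaries going up", {
  onset_for <- function(days) {
    cases <- profile_fixture()[1, ]
    cases$start_dt <- as.Date("2011-01-05")
    cases$event_dt <- as.Date("2011-01-05") + days
    ob <- onset_bins(cases, "crizotinib")
    ob$category[ob$count == 1]
  }
  expect_equal(onset_for(5), "0-7")
  expect_equal(onset_for(7), "7-28") # exactly 7 days goes to the upper bin
  expect_equal(onset_for(28), "28-60")
  expect_equal(onset_for(60), ">=60")
  expect_equal(onset_for(-3), "Unknown")
  # missing start date
  cases <- profile_fixture()[3, ]
  ob <- onset_bins(cases, "crizotinib")
  expect_equal(ob$category[ob$count == 1], "Unknown")
})

test_that("DILI profile restricts to consolidated DILI reports", {
  prof <- dili_profile(profile_fixture(), "crizotinib")
  expect_equal(prof$count[prof$block == "total"], 2L)
  sex <- prof[prof$block == "sex", ]
  expect_equal(sum(sex$count), 2)
  # mortality within the DILI subset: 1 of 2
  out <- prof[prof$block == "outcome", ]
  expect_equal(out$pct[out$category == "Death"], 50)
  # zero DILI reports: all-zero profile, not an error
  empty <- dili_profile(profile_fixture(), "ceritinib")
  expect_equal(empty$count[empty$block == "total"], 0L)
  expect_true(all(empty$count == 0))
})

test_that("printed cohort reference ratios recompute from counts", {
  ref <- alk_cohort_reference()
  totals <- ref[ref$block == "total", ]
  for (b in c("sex", "outcome", "reporter", "country", "onset")) {
    blk <- ref[ref$block == b, ]
    blk$total <- totals$count[match(blk$drug, totals$drug)]
    # the published brigatinib pharmacist percentage (6.89) does not
    # recompute from its count (521/7468 = 6.98); every other cell does
    recompute <- round2(100 * blk$count / blk$total, 2)
    off <- abs(recompute - blk$pct) > 0.011
    expect_lte(sum(off), if (b == "reporter") 1 else 0)
    # counts partition the report total (the published onset rows for
    # alectinib and lorlatinib do not sum to their totals; every other
    # block partitions exactly)
    full <- if (b == "onset") setdiff(totals$drug, c("alectinib", "lorlatinib"))
            else totals$drug
    sums <- tapply(blk$count, blk$drug, sum)
    expect_equal(as.vector(sums[full]),
                 totals$count[match(full, totals$drug)])
  }
})
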