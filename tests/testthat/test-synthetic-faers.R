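one_pt_config <- function(n = 100000, rrr = 5, seed = 11, dup = 0) {
  sim_config(
    n_reports = n,
    drug_vocab = data.frame(drug = "X", prob = 0.01),
    event_vocab = data.frame(pt = c("Y", "other"), prob = c(0.02, 0.98),
                             soc = "general disorders"),
    signals = if (rrr != 1) data.frame(drug = "X", pt = "Y", rrr = rrr),
    duplicate_rate = dup, pts_per_report = 1, seed = seed
  )
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(0), class = "faersignal_config_error")
  expect_error(
    sim_config(10, drug_vocab = data.frame(drug = c("a", "b"),
                                           prob = c(0.6, 0.6))),
    "sum to <= 1", class = "faersignal_config_error")
  expect_error(
    sim_config(10, event_vocab = data.frame(pt = "x", prob = 0.5, soc = "s")),
    "sum to 1", class = "faersignal_config_error")
  expect_error(sim_config(10, duplicate_rate = 1.2),
               "duplicate_rate", class = "faersignal_config_error")
  expect_error(
    sim_config(10, signals = data.frame(drug = "nope", pt = "nausea", rrr = 2)),
    "absent from drug_vocab", class = "faersignal_config_error")
  expect_error(
    sim_config(10, signals = data.frame(drug = "crizotinib", pt = "nausea",
                                        rrr = -1)),
    "reporting_rate_ratio", class = "faersignal_config_error")
})

test_that("generation is deterministic and duplicate-free when rate is 0", {
  cfg <- sim_config(500, duplicate_rate = 0, seed = 9)
  t1 <- generate_faers(cfg)
  t2 <- generate_faers(cfg)
  expect_identical(t1$demo, t2$demo)
  expect_identical(t1$reac, t2$reac)
  expect_identical(t1$drug, t2$drug)
  expect_identical(dplyr::n_distinct(t1$demo$caseid),
                   dplyr::n_distinct(t1$demo$primaryid))
})

test_that("duplicates are later re-submissions of existing cases", {
  cfg <- sim_config(2000, duplicate_rate = 0.2, seed = 21)
  tabs <- generate_faers(cfg)
  demo <- tabs$demo
  man <- attr(tabs, "manifest")
  expect_equal(dplyr::n_distinct(demo$caseid), man$n_cases)
  expect_equal(nrow(demo), man$n_primaryids)
  expect_gt(man$n_duplicates, 0)
  dups <- demo |>
    dplyr::summarise(n = dplyr::n(),
                     strictly_later = all(diff(sort(as.numeric(
                       as.Date(fda_dt, "%Y%m%d")))) > 0),
                     .by = caseid) |>
    dplyr::filter(n > 1)
  expect_true(all(dups$strictly_later))
  # child rows copied under the new primaryid
  dup_case <- dups$caseid[[1]]
  pids <- demo$primaryid[demo$caseid == dup_case]
  pts_by_pid <- lapply(pids, function(p) sort(tabs$reac$pt[tabs$reac$primaryid == p]))
  expect_true(all(vapply(pts_by_pid, identical, logical(1), pts_by_pid[[1]])))
})

test_that("injected-signal cell count matches the closed-form expectation", {
  cfg <- one_pt_config()
  ec <- expected_contingency(cfg, "X", "Y")
  # q = 0.02*5 / (1 + 0.02*(5-1)); a = n * 0.01 * q ~ 92.6
  expect_equal(ec$a, 100000 * 0.01 * 0.1 / 1.08, tolerance = 1e-12)
  expect_equal(ec$a, 92.59, tolerance = 1e-3)
  expect_equal(ec$a + ec$b + ec$c + ec$d, 100000)

  tabs <- generate_faers(cfg)
  cases <- add_canonical_drug(dedup_cases(assemble_cases(tabs)),
                              dict = data.frame(drug = "X", spelling = "x"))
  ct <- contingency_table(cases, "X", "Y", "PT",
                          hierarchy = data.frame(pt = c("y", "other"),
                                                 soc = "general disorders"))
  # binomial 4-sigma band around the expectation
  p <- 0.01 * 0.1 / 1.08
  sigma <- sqrt(100000 * p * (1 - p))
  expect_lt(abs(ct$a - ec$a), 4 * sigma)
})

test_that("expected_contingency obeys independence and conservation", {
  cfg <- one_pt_config(rrr = 1)
  ec <- expected_contingency(cfg, "X", "Y")
  expect_equal((ec$a * ec$d) / (ec$b * ec$c), 1, tolerance = 1e-12)
  expect_equal(ec$a + ec$b + ec$c + ec$d, cfg$n_reports)
  expect_error(expected_contingency(cfg, "X", "nope"),
               class = "faersignal_lookup_error")
  expect_error(expected_contingency(cfg, "nope", "Y"),
               class = "faersignal_lookup_error")
})

test_that("empirical cells track the oracle at large n", {
  cfg <- one_pt_config(n = 1000000, seed = 31)
  ec <- expected_contingency(cfg, "X", "Y")
  tabs <- generate_faers(cfg)
  cases <- add_canonical_drug(dedup_cases(assemble_cases(tabs)),
                              dict = data.frame(drug = "X", spelling = "x"))
  ct <- contingency_table(cases, "X", "Y", "PT",
                          hierarchy = data.frame(pt = c("y", "other"),
                                                 soc = "general disorders"))
  for (cell in c("a", "b", "c", "d")) {
    expect_lt(abs(ct[[cell]] - ec[[cell]]) / ec[[cell]], 0.05)
  }
})

test_that("tables round-trip through the on-disk FAERS format", {
  cfg <- sim_config(300, duplicate_rate = 0.1, concomitant_rate = 0.3,
                    pts_per_report = 2, seed = 41)
  tabs <- generate_faers(cfg)
  dir <- withr::local_tempdir()
  write_faers_tables(tabs, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_faers_dir(dir)
  expect_equal(attr(back, "rejects"), 0L)
  for (nm in c("demo", "drug", "reac", "outc", "indi", "ther")) {
    orig <- as.data.frame(tabs[[nm]])
    got <- as.data.frame(back[[nm]])
    expect_identical(nrow(got), nrow(orig))
    # compare as rendered text (numeric columns come back as character)
    for (col in names(orig)) {
      o <- as.character(orig[[col]])
      o[is.na(o) | o == ""] <- NA_character_
      expect_identical(as.character(got[[tolower(col)]]), o)
    }
  }
})
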