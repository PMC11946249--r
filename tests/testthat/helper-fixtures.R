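study_drugs <- c("crizotinib", "ceritinib", "alectinib", "brigatinib",
                 "lorlatinib")

# generator output -> analysis-ready deduplicated cases
make_cases <- function(cfg, consolidate = TRUE) {
  cases <- dedup_cases(assemble_cases(generate_faers(cfg)))
  if (consolidate) cases <- consolidate_dili(cases)
  add_canonical_drug(cases)
}

pooled_tables <- function(cases, drugs = study_drugs, level = "PT") {
  dplyr::bind_rows(lapply(intersect(drugs, unique(cases$drug)), function(d) {
    contingency_all(cases, d, level)
  }))
}

# hand-built toy case set: 4 reports covering every 2x2 cell
toy_cases <- function() {
  tibble::tibble(
    primaryid = c("1", "2", "3", "4"),
    caseid = c("1", "2", "3", "4"),
    fda_dt = as.Date("2020-01-01") + 0:3,
    drug = c("crizotinib", "crizotinib", NA, NA),
    pts = list("nausea", "rash", "nausea", "rash")
  )
}

# independent EBGM oracle: adaptive numerical integration of the posterior
# density p(lambda | a, E) ~ Poisson(a | lambda E) * prior mixture density,
# with no use of conjugate posterior updates
oracle_posterior <- function(a, e, prior) {
  dprior <- function(l) {
    prior$p * stats::dgamma(l, prior$alpha1, rate = prior$beta1) +
      (1 - prior$p) * stats::dgamma(l, prior$alpha2, rate = prior$beta2)
  }
  kern <- function(l) exp(stats::dpois(a, l * e, log = TRUE)) * dprior(l)
  upper <- max(20, (a / e) * 8, stats::qgamma(1 - 1e-12, prior$alpha2,
                                              rate = prior$beta2))
  # knots concentrated around the likelihood peak a/e so the adaptive
  # quadrature cannot miss a narrow posterior mode
  knots <- sort(unique(pmin(pmax(
    c(0, (a + 1) / e * c(0.1, 0.3, 0.5, 0.7, 0.85, 1, 1.15, 1.3, 1.6, 2,
                          3, 5, 8), upper), 0), upper)))
  piecewise <- function(f, to = upper) {
    ks <- sort(unique(c(knots[knots < to], to)))
    sum(vapply(seq_len(length(ks) - 1), function(j) {
      stats::integrate(f, ks[j], ks[j + 1], rel.tol = 1e-12,
                       subdivisions = 3000L)$value
    }, numeric(1)))
  }
  z <- piecewise(kern)
  list(
    mean_log = piecewise(function(l) log(l) * kern(l)) / z,
    quantile = function(p) {
      stats::uniroot(function(x) piecewise(kern, to = x) / z - p,
                     lower = upper * 1e-10, upper = upper,
                     tol = 1e-10)$root
    }
  )
}

oracle_ebgm <- function(a, e, prior) {
  post <- oracle_posterior(a, e, prior)
  c(ebgm = exp(post$mean_log), ebgm05 = post$quantile(0.05))
}

# random strictly-positive 2x2 tables
random_tables <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    a = sample(1:200, n, replace = TRUE),
    b = sample(1:5000, n, replace = TRUE),
    c = sample(1:5000, n, replace = TRUE),
    d = sample(100:100000, n, replace = TRUE)
  ) |>
    dplyr::mutate(n = a + b + c + d, expected = (a + b) * (a + c) / n)
}
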