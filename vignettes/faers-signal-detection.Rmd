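---
title: "Methods: disproportionality signal detection on spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection on spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as FAERS accumulate safety reports with
no denominator: we observe how often a drug–event pair is *reported*, not
how often it occurs. Disproportionality analysis sidesteps the missing
denominator by asking whether a pair is reported more often than the rest
of the database would predict. This package implements that design as a
complete pipeline — ingestion, case assembly, deduplication, event-term
consolidation, 2×2 contingency construction, four scoring algorithms,
threshold classification, ranking, overlap and cohort descriptives — with
a synthetic reporting-system generator so every stage is testable against
known ground truth.

The packaged defaults target the five ALK tyrosine kinase inhibitors used
in advanced ALK-rearranged non-small cell lung cancer, with particular
attention to drug-induced liver injury (DILI), but every vocabulary is a
plain CSV the user can replace.

## From raw tables to cases

**Ingestion.** FAERS quarterly extracts are `$`-delimited ASCII with
schema dialects that changed over the years (most visibly at 2014Q3, when
`ISR`/`CASE` became `PRIMARYID`/`CASEID` and `GNDR_COD` became `SEX`).
`read_faers_table()` lower-cases headers and maps the legacy names through
a synonym table, which the caller can extend per quarter via `column_map`.
Rows whose field count disagrees with the header are skipped and tallied,
never silently repaired; the tally surfaces in the pipeline run log.

**Assembly.** Tables join on `PRIMARYID`, one case per DEMO row. Ages are
normalized to years with fixed divisors (DEC ×10, YR ×1, MON ÷12,
WK ÷52.1775, DY ÷365.25, HR ÷8766 — the FAERS documentation conventions,
kept as testable constants). Reports with no reaction row are dropped and
tallied: the analysis unit is a report–event pair, so an event-less report
can contribute to no margin. Child rows whose key is absent from DEMO are
tallied as orphans. The run log's accounting identity
(ingested = analyzed + duplicates removed + event-less dropped) is asserted
in the tests.

**Deduplication.** The same safety case is frequently re-submitted.
Following the FDA recommendation, within each `CASEID` group the report
with the latest `FDA_DT` is kept; among ties the numerically higher
`PRIMARYID` wins (lexicographic after left zero-padding when ids are not
numeric — FAERS ids are numeric strings, but the comparison rule must be
total). A report with a missing `FDA_DT` loses every tie-break rather than
aborting the run: real extracts have gaps, and demotion is the conservative
choice. The operation is idempotent, and on synthetic data it recovers the
generator's distinct-case count exactly.

**DILI consolidation.** Before any drug search or counting, every PT in
the liver-injury lexicon is rewritten to the single event `"DILI"` and the
report's PT set deduplicated, so a report listing both ALT and AST
elevations contributes one DILI event, not two. The packaged lexicon lists
40 laboratory and clinical liver-injury PTs (transaminase, bilirubin and
alkaline-phosphatase elevations, hepatic failure, hepatitis terms,
hepatotoxicity, cholestasis, jaundice, ...) adapted from published DILI
case definitions in pharmacovigilance studies. The case definition is
deliberately config, not code: editing one CSV changes the analysis.

**Vocabularies.** Drug matching is exact after case-folding and
whitespace squishing, against generic plus brand-name spellings; fuzzy
matching is out of scope. MedDRA is licensed and cannot be redistributed,
so the packaged PT→SOC hierarchy is *synthetic*: it covers the simulation
vocabulary, the DILI lexicon and the terms used in examples, and users
supply their own MedDRA export for real analyses.

## The 2×2 table

For a drug–event pair, reports partition into `a` (drug and event), `b`
(drug only), `c` (event only) and `d` (neither); `N = a+b+c+d` and the
expected count under independence is `E = (a+b)(a+c)/N`. Counting is per
report: a report with several qualifying PTs counts once in the event
margin, and at SOC level a report qualifies when at least one PT maps to
the SOC. The comparator is the full ingested database by default; a
`comparator = "other_study"` option restricts the background to the other
study drugs, because the choice materially changes `c` and `d` and should
be explicit rather than implicit.

## The four algorithms and their thresholds

The conventional forms are used throughout:

* ROR = ad/bc, 95% Wald CI on the log scale. Undefined when any cell is
  zero — no continuity correction is applied, ever; silent corrections
  change borderline signals, and the minimum-count rule below makes the
  zero-cell case largely moot.
* PRR = [a/(a+b)]/[c/(c+d)]; Pearson χ² without Yates correction (a
  Yates-corrected variant is available for sensitivity analysis).
* BCPNN information component, discussed below.
* MGPS EBGM, the DuMouchel empirical-Bayes shrinkage estimator.

Signal thresholds: ROR fires at a ≥ 3 with CI lower bound > 1; PRR at
a ≥ 3, PRR ≥ 2, χ² ≥ 4; BCPNN at IC025 > 0; MGPS at EBGM05 > 2. These are
the established criteria in the FAERS literature, and they uniquely
reproduce the significance pattern of the reference tables shipped with
the package: an EBGM05 of 1.88 is unstarred while 2.09 is starred, an
IC025 of −0.42 is unstarred, and applying the conjunction to the reported
DILI statistics classifies exactly crizotinib, ceritinib and alectinib as
DILI-associated. The combined flag (all four algorithms) trades the
frequentist methods' sensitivity against Bayesian shrinkage's specificity.
No multiple-testing adjustment is applied: classification is
threshold-based, matching field practice.

### MGPS: fitting and posterior summaries

The model: `a ~ Poisson(λE)` with `λ ~ p·Γ(α₁,β₁) + (1−p)·Γ(α₂,β₂)`.
Marginally each count is a two-component negative-binomial mixture, and
`fit_mgps_prior()` maximizes the summed log marginal likelihood by BFGS on
log/logit-transformed hyperparameters from the conventional start
(0.2, 0.1, 2.0, 4.0, 1/3) plus four fixed perturbed starts; the best of
the five is kept, making the fit deterministic given the data. At least 50
tables with E > 0 are required — with fewer, five hyperparameters are not
meaningfully estimable. The pipeline fits one prior on the pooled PT-level
tables of all study drugs (a pre-fitted prior, e.g. from a full database,
can be passed instead; both conventions exist in practice and the choice
is surfaced rather than hidden).

Two numerical notes. First, on data with little overdispersion the
likelihood pushes component shapes toward infinity (a gamma collapsing to
a point mass); this is the correct maximum and the posterior summaries
remain well defined, but the quantile root-finder defensively widens its
bracket for such near-degenerate fits. Second, the posterior given `(a, E)`
is again a two-component gamma mixture with components `Γ(αₖ+a, βₖ+E)` and
weights proportional to prior weight times marginal likelihood, so
EBGM = exp(Σ wₖ(ψ(αₖ+a) − ln(βₖ+E))) uses the digamma function exactly,
and EBGM05 solves the monotone mixture CDF equation by root-finding to
1e−8. Tests verify both against an independent adaptive-quadrature oracle
that integrates the Poisson-times-prior kernel directly (with quadrature
knots concentrated around a/E — a naive single-interval integration can
miss a narrow posterior mode and wrongly indict the exact computation).

### BCPNN: the `paper_compat` convention

The reference signal tables this package reproduces satisfy, in every
printed row, IC = log₂(EBGM) to 2 decimals and IC − IC025 = 1.66–1.67
regardless of the report count. That is not any standard BCPNN posterior
interval we know (a credible interval's width must shrink with `a`), but
encoding it is required to reproduce the tables, so the default
`bcpnn_mode = "paper_compat"` computes IC = log₂(EBGM), IC025 = IC − 1.66
— documented as a reproduction convention, not an endorsement. The
`credible_interval` mode instead takes IC025 as log₂ of the posterior
2.5th percentile of λ, which is the statistically preferred bound; under
it, BCPNN flags become count-sensitive as they should be.

## Ranking, overlap, profiles

Top-k ranking first drops PTs matching exclusion patterns. The packaged
lists cover death terms, COVID-19 terms and an explicit malignancy /
disease-progression list; by default only death and COVID-19 are active,
because published top-30 tables routinely rank metastasis PTs even when
the stated policy excludes malignancy-related events — the list is the
user's editorial decision. Surviving rows are filtered to combined
signals (configurable to any-flag), sorted by report count descending with
EBGM then PT name as tie-breaks, and truncated.

Signal overlap returns, for every nonempty drug subset, the count of
events signalled in exactly that subset — the region counts of a Venn
diagram; counts sum to the union size by construction.

Cohort profiles mirror the descriptive tables of FAERS studies. FAERS
allows several outcome codes per report while published tables show
mutually exclusive percentages, so one category is chosen per report by
severity precedence Death > Hospitalization > Life threatening >
Disability > Other serious (pooling OT, CA, RI) > Unknown. Time-to-onset
is event date minus earliest therapy start, binned half-open into [0,7),
[7,28), [28,60), [60,∞) — published bin labels like "0–7"/"7–28" overlap
at the boundary, forcing a convention, and boundaries here go to the upper
bin. Ages are summarized over non-missing values with the missing count
reported; Unknown categories absorb all missingness so every block's
counts sum to the drug's report total. All reported statistics round to 2
decimals, half away from zero.

## The synthetic reporting system

`generate_faers()` draws, per base case: one primary-suspect drug from the
configured marginals (remainder mass goes to background drugs); a PT count
from a shifted Poisson (1 + Poisson(mean − 1)) and PTs without replacement
from the background distribution tilted by any injected signal,
`q_d(pt) ∝ background(pt) × rrr(d, pt)`; demographics with configurable
age and date missingness and mixed age-unit encodings to exercise
normalization; receipt dates uniform in the study window with exponential
therapy-to-event onset (mean 30 days); outcome codes; and, with the
configured probability, a duplicate re-submission that copies all child
rows under a new PRIMARYID with a strictly later FDA_DT — so deduplication
correctness is decidable from keys alone. Generation is deterministic
given the seed.

`expected_contingency()` returns the exact expected cells with no
sampling. With one PT per report the event-inclusion probability is
exactly the tilted background `q_d(pt)`; with a mean of `m > 1` PTs the
independent-draw form `1 − (1−q)·exp(−(m−1)q)` is exact for draws with
replacement and a close approximation for the without-replacement sampler,
so closed-form oracle tests use one-PT configurations.

What the generator does *not* emulate: drug–drug interaction structure,
demographic confounding of drug–event associations (demographics are
independent of the signal process), reporting waves after approval (the
Weber effect), or verbatim-text noise in drug names beyond the configured
spellings. Passing tests therefore demonstrate algorithmic correctness and
operating characteristics under a clean generative model, not robustness
to real-world reporting biases.

## Simulation studies and their sizes

The acceptance studies run the full pipeline on 20 seeded replicates of
100,000 reports each, a size at which the five study drugs carry roughly
800–2,000 reports apiece — comparable in order of magnitude to per-drug
cohorts in real FAERS analyses while keeping a full study under a few
minutes on one CPU. On all-null data (all reporting-rate ratios 1) the
combined classifier's empirical false-positive rate across ~2,700
drug–PT pairs is 0; with injected rrr = 5 signals whose expected count
exceeds 20, recovery is 100% across replicates. The brute-force oracle
agreement for ROR/PRR/χ²/O÷E is at machine precision over 1,000 random
tables, and EBGM/EBGM05 agree with numerical posterior integration to
better than 1e−6 over 100 random tables and priors.

## Known limitations

Disproportionality measures reporting association, not causation or
incidence. No Weber-effect (time-stratified) adjustment is performed, so
signals for recently approved drugs may be inflated. No confounding
adjustment (age, sex, indication) is attempted. The `paper_compat` BCPNN
interval is a reproduction convention with no probabilistic
interpretation. The packaged MedDRA hierarchy is synthetic and must be
replaced for production use, and the DILI lexicon, drug dictionary and
exclusion lists are editable case definitions whose choices the analyst
owns.
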