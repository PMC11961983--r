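---
title: "Disproportionality methods in pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods in pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(dplyr)
```

This vignette documents the statistical model behind `pvsignal`, the exact
formulas it implements, the numerical choices that affect reproducibility,
and what the bundled synthetic-database generator does and does not emulate.

## The data model and its assumptions

Spontaneous reporting databases such as FAERS hold voluntary reports of
suspected adverse drug reactions. Each *case* may be reported several times
(follow-ups, duplicate submissions); each report lists one or more drugs
with role codes and one or more reaction terms coded as MedDRA preferred
terms (PTs). Disproportionality analysis treats the database as a large
cross-classification of drug–event pairs and asks whether a given pair is
over-represented. It rests on assumptions worth stating:

* Reporting, not incidence. All quantities are ratios of *reporting* rates.
  Under-reporting, stimulated reporting, and channeling bias all move the
  estimates; nothing in the arithmetic corrects for them.
* The comparator is "everything else in the database". The background rates
  reflect the mix of drugs and indications in the reporting system, not a
  population at risk.
* Event-level counting. The analysis unit is the unique (deduplicated
  report, PT) pair. A report mentioning three PTs contributes three events;
  a PT repeated within one report contributes one.

### Deduplication and exposure

`dedup_reports()` keeps, within each case identifier, the report version
with the latest FDA receipt date, breaking ties by the highest report
identifier — the standard FAERS convention. A report counts as
target-drug-exposed only when the drug record carries the primary-suspect
role code (`select_target_reports()`); concomitant and interacting
mentions are ignored for exposure, which sharpens specificity at the cost
of some sensitivity.

## Estimators

For a term, with `a` target-drug events on the term, `b` other target-drug
events, `c` comparator events on the term, `d` the rest, and
`N = a + b + c + d`:

**Reporting odds ratio.** `ROR = (a d)/(b c)` with the Wald interval
`exp(log ROR ± 1.96 · sqrt(1/a + 1/b + 1/c + 1/d))`.

**Proportional reporting ratio.** `PRR = [a/(a+b)] / [c/(c+d)]` with the
row-conditioned standard error
`sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))`, accompanied by the Pearson
chi-squared statistic of the 2×2 table **without** Yates continuity
correction. The uncorrected statistic is the one conventionally paired with
the PRR ≥ 2 / χ² ≥ 4 rule; at pharmacovigilance sample sizes the continuity
correction is negligible anyway, but at small counts it would change
borderline decisions, so the choice is fixed and tested against
`chisq.test(correct = FALSE)`.

**Information component.** `IC = log2(a N / ((a+c)(a+b)))`, the base-2 log
of the observed-to-expected ratio under independence. Two interval methods
are offered:

* `"se"` (default): a Wald interval on the log2 scale, the natural-scale
  standard error divided by `ln 2`. This is the method whose bounds are
  consistent with the EBGM bounds below (IC025 = log2(EBGM05)).
* `"bcpnn-bayes"`: the closed-form credible bound of the Bayesian
  confidence propagation neural network,
  `IC* = log2((a + 0.5)/(E + 0.5))` with
  `IC025 = IC* − 3.3 (a + 0.5)^{-1/2} − 2 (a + 0.5)^{-3/2}`, which shrinks
  harder at small counts. It is provided because IC-based screening in
  VigiBase-style workflows uses it; the default stays `"se"` because the
  reference analysis's printed IC values equal `log2(EBGM)` exactly, which
  only the unshrunk form satisfies.

**EBGM.** `pvsignal` reports `EBGM = a N / ((a+c)(a+b))` — the raw relative
reporting ratio — with Wald bounds on the log scale, *not* the
gamma-Poisson-shrunk posterior geometric mean of the full MGPS procedure.
This is deliberate: the reference results this package reproduces satisfy
`IC = log2(EBGM)` to the printed precision on every row, which identifies
the unshrunk statistic. At the large counts typical of SOC-level rows,
shrinkage is immaterial; at PT-level counts near the `a ≥ 3` floor, the
unshrunk EBGM05 is anti-conservative relative to MGPS, and users comparing
against MGPS software should expect differences there.

### The combined significance rule

`signal_thresholds()` encodes the conjunction used throughout: a term is a
significant signal iff `a ≥ 3` **and** ROR 95% lower bound > 1 **and**
(PRR ≥ 2 with χ² ≥ 4) **and** IC025 > 0 **and** EBGM05 > 2. Requiring all
four algorithms is conservative by construction; each threshold is a
configurable field. Undefined estimates (any required zero cell) fail their
criterion rather than erroring — a zero cell means the data cannot support
the claim, not that the pipeline should stop. No Haldane–Anscombe 0.5
correction is applied to point estimates; the `"bcpnn-bayes"` IC bound is
the one place a +0.5 enters, as part of that method's definition.

## Back-solving published margins

Published disproportionality tables usually print `a`, the drug's event
total, and the estimates — not the comparator cells. `solve_margins()`
recovers `c` and `d` from `(a, row total, PRR, χ²)`: the PRR pins the
comparator event *rate*, leaving one unknown, the comparator scale
`M = c + d`, which the χ² statistic determines. Numerically, χ² is monotone
increasing in `M` but bounded above by the asymptote
`n₁ (p₁ − p)² / (p (1 − p))`, so a requested χ² beyond the asymptote has no
solution and raises a bracketing error. Because the statistic flattens near
the asymptote, a residual-based stopping rule terminates too early; the
solver instead bisects on `log10(M)` over `[10³, 10¹⁰]` for a fixed 100
iterations (interval convergence far below 0.1%), then warns if the
achieved χ² still misses the target by more than the tolerance. Round-trip
accuracy is property-tested at 0.1%.

```{r backsolve}
sol <- solve_margins(a = 7744, row_total = 44295, prr = 3.35, chi2 = 13409.5)
evaluate_signal(sol$a, sol$b, sol$c, sol$d)[, c("ror", "ror_lower",
                                                "ror_upper", "ic", "ebgm")]
```

## Time to onset

`collect_valid_onsets()` computes, per target-exposed report, event date
minus the *earliest* therapy start of the target drug (therapy records are
joined to drug records on the report id and drug sequence, so only the
target drug's therapy lines count). Decisions that affect the numbers:

* Day 0 is valid: an event on the start date is a real same-day onset,
  not an error. Negative durations are excluded as `"negative duration"`.
* FAERS dates come at day, month, or year precision. Onset arithmetic
  needs day precision on both ends; anything less is excluded as
  `"partial date"`, alongside `"missing start"` and `"missing event
  date"`. Exclusion reasons are kept as an attribute so attrition is
  auditable.
* `summarize_onsets()` uses quantile type 7 (R's default) for the median
  and quartiles, and bins durations as `[0,30], (30,60], (60,90],
  (90,120], (120,180], (180,∞)` — closed on the right except the first
  bin, so day 30 is "within 30 days".

## The synthetic generator

`generate_database()` emits a five-table database (demographics, drugs,
reactions, therapy dates, outcomes) in the dollar-delimited dialect the
ingestion functions read, plus a ledger of ground truth (per-PT counts,
injected duplicates and their designated survivors, true onset values).
Calibration targets, all overridable via `generator_config()`:

* events per report: zero-truncated Poisson with mean ≈ 2.76;
* onsets: log-normal with median 36 days and `sdlog = 1.8`, putting the
  quartiles near 11 and 126 days;
* demographics, reporter mix, countries, outcomes and a 95.8% seriousness
  rate matching a large azacitidine reporting cohort;
* duplicate injection: a configurable fraction of cases receives a second
  report version with a later-or-equal receipt date and incremented report
  id, so the ledgered survivor is always the duplicate — exercising the
  dedup rule's date and tie-break branches;
* date degradation: configurable rates of missing and partial therapy and
  event dates, plus a small rate of deliberately inconsistent onsets.

Determinism is by `withr::with_seed`; the same configuration and seed yield
byte-identical files. The generator emulates the *statistical shape* of a
reporting database — it does not emulate FAERS field vocabularies beyond
the columns the pipeline reads, narrative text, or real drug co-occurrence
structure, and its background drugs are exchangeable placeholders.

## Limitations

Beyond the reporting-bias caveats above: the unshrunk EBGM is
anti-conservative at small counts; SOC-level tests inherit whatever PT→SOC
dictionary is supplied (the bundled toy dictionary covers only the terms
used in examples); and the combined rule's conjunction makes its false
negative rate sensitive to the weakest criterion at small `a`. For
regulatory-grade screening, pair this package's output with clinical review
and, where shrinkage matters, an MGPS implementation.
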