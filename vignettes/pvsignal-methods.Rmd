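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
```

## The problem

Spontaneous-report databases such as FAERS collect voluntary reports of
suspected adverse drug events (ADEs). They have no denominator: we never
observe how many patients took a drug without an event. Signal detection
therefore works by *disproportionality*: for a focal drug and a MedDRA
preferred term (PT), compare how often the pair is reported against how often
the PT is reported with all other drugs. The unit of analysis is the
deduplicated report, arranged in a fourfold table:

|                | event          | no event       |
|----------------|----------------|----------------|
| focal drug     | a              | b              |
| all other drugs| c              | d              |

with `N = a + b + c + d`. `pvsignal` builds these tables from FAERS-dialect
quarterly files (or from its own synthetic generator), computes four
disproportionality statistics, and tiers each PT by consensus across them.

## The four algorithms

**ROR.** The reporting odds ratio `ROR = ad / bc` with
`SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)` and 95% interval
`exp(ln ROR ± 1.96 SE)`. Signal rule: `a > 3` and CI lower bound `> 1`.

**MHRA.** The proportional reporting ratio
`PRR = [a/(a+b)] / [c/(c+d)]` together with the Yates-corrected chi-squared
`χ² = N (|ad − bc| − N/2)² / [(a+b)(c+d)(a+c)(b+d)]` (continuity term floored
at zero). Signal rule: `a > 3`, `PRR > 2`, `χ² > 4`.

**BCPNN.** The information component `IC = log2[aN / ((a+b)(a+c))]` measures
observed-to-expected co-reporting in bits. Its Bayesian posterior expectation
under a Dirichlet prior on the joint probability and Beta priors on the
margins is

```
E(IC) = log2[ (a + γ11)(N + α)(N + β) / ((N + γ)(a + b + α1)(a + c + β1)) ]
γ     = γ11 (N + α)(N + β) / ((a + b + α1)(a + c + β1))
```

and the decision bound is `IC025 = E(IC) − 2·sqrt(V(IC))`. Signal rule:
`IC025 > 0`.

**MGPS (as reported here).** `EBGM = aN / ((a+c)(a+b))`, the relative
reporting ratio, with the log-normal interval
`exp(ln EBGM ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Signal rule:
`EBGM05 > 2`. This is deliberately the *unshrunk* observed-to-expected
ratio — the full DuMouchel gamma-Poisson shrinker with EM-fitted mixture
hyperparameters is out of scope, and the `shrunk = FALSE` attribute on the
result records that. For small `a` this statistic is more optimistic than a
shrunk EBGM would be; the consensus tier compensates, since BCPNN does
shrink.

```{r reference}
tab <- contingency_table(20, 80, 100, 9800)
ror(tab)
prr_chi2(tab)
bcpnn_ic(tab)
ebgm(tab)
```

## Design choices

**BCPNN priors.** The classical choice `γ11 = 1`, `α1 = β1 = 1`,
`α = β = 2`, which makes the prior expectation of IC zero. The variance uses
the standard first-order closed form

```
V(IC) = (1/ln 2)² [ (N − a + γ − γ11) / ((a + γ11)(1 + N + γ))
      + (N − (a+b) + α − α1) / ((a + b + α1)(1 + N + α))
      + (N − (a+c) + β − β1) / ((a + c + β1)(1 + N + β)) ]
```

The test suite validates `IC025 = E(IC) − 2·sqrt(V(IC))` against a
Monte-Carlo oracle that draws 10⁶ samples from the independent Beta
posteriors of the joint and marginal reporting probabilities; agreement is
within ±0.05 bits on random tables with cells up to 500.

**Strict thresholds.** All criteria are strict inequalities: `a > 3` means
`a ≥ 4`, `IC025 = 0` and `EBGM05 = 2` fail. Undefined statistics (zero cells
without correction) fail their criterion. Thresholds are configurable via
`signal_criteria()`.

**Zero cells.** By default a zero cell makes the ROR and the EBGM interval
undefined (and hence negative under any criterion). The optional
Haldane–Anscombe correction (`correction = TRUE`) adds 0.5 to every cell of
an affected table. The BCPNN needs no correction — the prior regularises —
and `PRR` returns `Inf` when `c = 0` with `a > 0`, which is mathematically
faithful and conservative only through the paired χ² requirement.

**Consensus instead of multiplicity adjustment.** No multiple-testing
correction is applied — deliberate, matching disproportionality practice.
A PT flagged by at least one algorithm is a *positive* signal; a PT flagged
by all four is a *strong* signal, and the strong tier is the headline set.
The four-way intersection is the false-positive control: the null-calibration
test shows that on independence-only databases the strong rate is ≲1% of
tested PTs.

**Counting unit.** A report contributes at most once to the focal row and at
most once to the event column, however many times a PT or drug is repeated
within it, so cells always sum to the report count. Report-level counting is
the package default; studies that count case–event pairs can pre-expand
their data before table construction.

**Deduplication.** FAERS carries multiple versions per case; `deduplicate()`
keeps, per `case_id`, the record with the largest version key and breaks
ties by the lexicographically larger raw record identifier — the standard
latest-version convention. The operation is idempotent and commutes with
drug selection when versions do not disagree about the drug.

**SOC rollup.** Each PT maps to exactly one system organ class (the
primary-SOC convention), so SOC totals conserve PT totals. MedDRA is
licensed; the bundled `toy_meddra_map()` covers only the synthetic default
PTs, and real analyses must supply a `pt,soc,soc_code` CSV.

**Onset time.** Onset is `event_date − therapy_start` (earliest therapy
record), bucketed into half-open 30-day intervals: day 0 falls in bucket 1,
day 30 opens bucket 2. Negative and missing onsets are excluded from the
buckets but counted separately; records with missing dates still contribute
to signal detection.

## The synthetic generator

`generate_reports()` emulates the *marginal* structure a disproportionality
analysis consumes:

- focal-drug membership is Bernoulli with `focal_drug_fraction`; focal
  reports carry exactly one focal primary-suspect mention, other reports a
  primary suspect from a background drug pool, so `b` and `d` are populated;
- each background PT is an independent Bernoulli given drug status, with
  injected signal PTs multiplying their background rate by a known reporting
  ratio (capped at 1) in focal reports;
- a report whose draws produced no event receives a designated filler PT
  outside the background set. This keeps the spontaneous-report invariant
  (every report lists ≥1 reaction) *and* keeps the closed-form cell
  expectations of `expected_cells()` exact for every background PT —
  redrawing zero-event reports instead would condition all per-PT
  probabilities on "≥1 event" and, in the single-PT limit, force the PT into
  every report;
- serious reports (probability `serious_fraction`, default 0.304) receive
  one outcome code from configurable weights (defaults proportional to the
  hospitalisation / other-serious / death / life-threatening / disability
  composition of a recent antiseizure-drug safety profile); country codes
  default to a US-dominated mixture; onset days are geometric with mean 30
  days, reproducing first-month clustering;
- all randomness flows from a single seed: the same `sim_config` is
  bit-reproducible.

What it does **not** model: drug co-prescription structure, correlated
events within a report, reporter-specific duplication patterns, secular
trends in reporting rates, or event-dependent seriousness. Passing tests on
synthetic data therefore demonstrate correctness of the *computational
pipeline* and its statistical calibration under independence — not that any
particular real-world association is causal or would be detected at these
rates.

```{r recovery}
cfg <- sim_config(n_reports = 2000, seed = 11)
run <- run_pipeline(sim = cfg)
run$venn
```

## Validation problem sizes

The shipped test suite exercises: exact-value checks on hand-derived tables;
a 1,000-table comparison of the point statistics against big-rational
arithmetic (12 significant digits); the BCPNN Monte-Carlo oracle on 20
random tables at 10⁶ draws each; 100 null databases of 10,000 reports for
calibration (≤1% strong PTs); 100 seeded replicates of a five-signal
recovery scenario with expected `a ≈ 25` per signal (≥95% full recovery);
and 20 write/read/deduplicate round-trips. These sizes give Monte-Carlo
error comfortably inside every asserted tolerance while keeping the suite
quick to run.

## Limitations

Disproportionality quantifies reporting imbalance, not risk: no causal or
incidence interpretation attaches to any statistic here. The unshrunk EBGM
overstates small-count signals relative to MGPS proper. The FAERS dialect
reader targets the `$`-delimited ASCII layout only (no XML), and drug-name
matching is string-based — multi-ingredient normalisation against a drug
dictionary is out of scope.
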