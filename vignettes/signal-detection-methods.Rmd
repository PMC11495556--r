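---
title: "Disproportionality signal detection on spontaneous-report data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
post-marketing reports in which a reporter names one or more drugs (with a
role code: primary suspect PS, secondary suspect, concomitant, interacting)
and one or more reactions coded as MedDRA preferred terms (PTs). Reporting
is voluntary and denominator-free, so incidence cannot be estimated; what
can be estimated is *disproportionality*: whether a drug-event pair is
reported more often than the rest of the database would predict. This
package implements the standard screening workflow for a single target
drug: ingest the quarterly tables, keep one report per case, keep reports
where the target drug is the primary suspect, and screen every PT (and
every System Organ Class, SOC) with four classical algorithms.

## The 2x2 table and the four algorithms

For one event term the database collapses to

|            | event | other events |
|------------|-------|--------------|
| target     | `a`   | `b`          |
| all others | `c`   | `d`          |

with `N = a+b+c+d`. The four statistics, in the simplified forms used
throughout the pharmacovigilance screening literature, are

* **ROR** `= ad/(bc)`, with the log-symmetric Wald interval
  `exp(ln ROR ± 1.96·sqrt(1/a+1/b+1/c+1/d))`;
* **PRR** `= a(c+d)/(c(a+b))`, paired with the uncorrected Pearson
  chi-square of the table;
* **IC** (BCPNN information component)
  `= log2(aN/((a+b)(a+c)))`, with `IC025 = IC − 2·sqrt(V)`;
* **EBGM** `= aN/((a+b)(a+c))` with
  `EBGM05 = exp(ln EBGM − 1.96·sqrt(1/a+1/b+1/c+1/d))`.

A term is a **significant signal** only when all four criteria hold at
once: `ROR` lower bound `> 1` with `a ≥ 3`; `PRR ≥ 2` with `χ² ≥ 4` and
`a ≥ 3`; `IC025 > 0`; `EBGM05 > 2`. A significant signal absent from the
supplied label-PT list is flagged **unexpected**.

Three numerical notes:

1. **IC equals log2(EBGM) by construction.** Both are the same
   observed/expected ratio on different scales. This identity is asserted
   in the test suite on random tables and against published table pairs.
2. **The IC variance.** The screening convention `IC025 = E(IC) − 2√V(IC)`
   leaves `V` open. We use the Bate et al. (1998) Beta/Dirichlet moment
   approximation with all prior hyperparameters equal to 1. Against an
   exact Monte-Carlo Dirichlet posterior (a flat prior over the four
   cells), the moment bound is mildly *conservative*: for the table
   (10, 90, 100, 9900) the closed form gives 2.244 while the exact 2.5%
   posterior quantile is 2.367. The test suite pins the closed form to
   within 0.3 bits of, and below, the Monte-Carlo quantile.
3. **z = 1.96 verbatim.** The screening formulas print 1.96, not
   `qnorm(0.975)` = 1.959964. We use the printed constant so that results
   agree digit-for-digit with published tables and with the independent
   test oracle.

### Zero cells and undefined rows

The ratio formulas are undefined when `b`, `c` or `d` is zero. The default
policy (`zero_cell = "undefined"`) flags such rows non-computable — they
get `NA` statistics and fail every criterion — because silent smoothing
hides data sparsity. An optional Haldane correction
(`zero_cell = "haldane"`) adds 0.5 to all four cells of affected tables.
`a = 0` is never a signal under either policy.

### Counting unit

Published screening tables rarely state whether `N` counts *reports* or
*(report, event) pairs*; with several PTs per report the two differ. The
unit is explicit configuration here. The default is `drug_event_pair`
(margins count distinct report-term pairs), which keeps the margins
consistent across PT rows; `report` counts each report once per term. At
SOC level a report contributes at most once per SOC even when several of
its PTs map there, under either unit.

### A non-obvious property

Strict monotonicity of the statistics in `a` (holding `b`, `c`, `d`
fixed) holds universally for ROR and PRR but **not** for the simplified
EBGM/IC: `d(log EBGM)/da = 1/a + 1/N − 1/(a+b) − 1/(a+c)` turns negative
when the target margins rival the comparator ones (e.g.
(5000, 1, 1, 5000)). Every realistic spontaneous-report table has
`a ≪ c, d`, where monotonicity does hold; the property test asserts it in
that regime and documents the counterexample.

## Preprocessing rules

* **Deduplication.** FAERS carries multiple versions of a case (same
  `caseid`, new `primaryid`). We apply the FDA-recommended deterministic
  rule: per `caseid` keep the latest `fda_dt`, ties broken by the largest
  numeric `primaryid`; a missing `fda_dt` sorts earliest. Deduplication is
  idempotent and order-independent, and runs before primary-suspect
  filtering (the per-case rule makes the order immaterial; the manifest
  follows the study-flow order).
* **Drug matching.** Trim/upper-case-normalised exact equality of
  `drugname` or `prod_ai` against the target name list; a substring mode
  is opt-in because it also catches combination products.
* **Terms.** PTs are normalised and mapped to exactly one primary SOC via
  a user-supplied two-column map (a stand-in for licensed MedDRA).
  Unmapped PTs stay in PT-level screens — the statistics need no SOC —
  but are excluded from SOC-level screens and reported in the manifest.
* **Exclusions.** Terms conventionally judged unrelated to drug treatment
  (product issues; injury, poisoning and procedural complications;
  surgical and medical procedures) can be dropped before the significant
  count; the default list holds those three SOC names and is a plain text
  file in production use.

## Descriptive characteristics

One row per case: gender; age in years (unit-converted from decades,
months, weeks, days or hours; a missing unit is read as years with a
warning) binned as `<18`, `18~64`, `65~85` (85 inclusive, integer rounding
first), `>85`, `Unknown`; reporter type (`MD`→Physician, `PH`→Pharmacist,
`CN`→Consumer, `HP` and `OT`→Health Professional); top-N reporting
countries with the remainder pooled; reporting year (from `fda_dt` by
default, since it is always populated); and one serious outcome per case.
Multi-outcome cases collapse under a severity-ordered precedence (death
first: `DE > LT > DS > CA > RI > HO > OT`), exposed as configuration — a
reporting convention, not a recoverable fact of the data. Counts within
each category sum to the cohort size; `Unknown` absorbs missingness.

## Time to onset

Onset is `event date − earliest target-drug therapy start date` in whole
days, computed only when both dates have full day precision. Exclusions
carry reason codes (`missing_start`, `missing_event`, `partial_date`,
`negative`). Negative durations are treated as impossible false positives
and excluded; same-day onset (0 days) is retained. The summary reports the
median (mean of the two middle values for even counts) and right-closed
30-day-based bins (0–30, 31–60, 61–90, 91–180, 181–360, >360).

## The synthetic world

`synthetic_config()` describes a stated world, not tuning dials. Defaults:

* `n_reports = 300,000` cases, `p_target = 0.02`. The target share is
  deliberately larger than a single rare drug's share of the real
  database (~1e-3): with a planted rare PT (baseline 1e-3) the expected
  target case count must reach the recovery-check threshold (expected
  `a ≥ 50`) at desk scale, which 0.02 × 300,000 × ~3 events achieves
  (~190 expected cases).
* A 200-term Zipf PT vocabulary (`1/j` weights) mapped onto 20 SOCs;
  events per report are zero-truncated Poisson with rate 3 (mean ≈ 3.16);
  for target-exposed reports the weights are multiplied by the planted
  rate ratios and renormalised, and events are drawn without replacement
  by exponential ranking keys.
* Log-normal onset times with median 60 days and log-sd 1; therapy start,
  event and receipt dates placed consistently; 10% of present dates
  degraded to month precision, and FAERS-typical missingness elsewhere
  (60% of ages missing, ~82% of reports without an outcome code; 95%
  male, elderly, consumer-reported, US-dominated — the demographic
  profile of an androgen-deprivation-therapy cohort).
* 5% duplicate case versions: re-emissions with `caseversion` 2, a new
  `primaryid` and `fda_dt + 30` days, linked in the ground truth.

Because target-report event weights are renormalised, a planted ratio
`λ` is recovered not as `λ` itself but as
`r/(p_target·r + 1 − p_target)` with `r = λ / Σ(baseline·λ)` — the exact
observed/expected value against pooled margins. `planted_truth_check()`
applies this adjustment; the default recovery tolerance is ±30% relative,
with a 2% false-positive budget for null PTs under the four-way
conjunction.

**What a green synthetic run does not establish:** reports are sampled
independently (no co-prescription correlation, no masking/competition
bias, no secular reporting trends, no stimulated-reporting waves), names
are clean apart from case noise, and duplicates are exact re-emissions
rather than the fuzzy near-duplicates of real data. Recovery of a planted
ratio therefore validates the pipeline's arithmetic and bookkeeping, not
the epidemiological reliability of disproportionality on real data.

## Known limitations

* The simplified EBGM is the plain observed/expected ratio: no
  gamma-Poisson mixture fitting, hence no shrinkage of small-count cells
  beyond what the four-way criterion conjunction provides.
* Published screening tables sometimes print interval bounds inconsistent
  with their own stated formulas (implied standard errors smaller than
  the `1/a` floor); this implementation follows the formulas, not any
  particular printed interval.
* No multiple-testing adjustment is applied, matching screening practice:
  the conjunction of four criteria is the only guard.
* Probabilistic record linkage for duplicates, MedDRA LLT coding of
  verbatim terms, and multi-axial SOC assignment are out of scope.
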