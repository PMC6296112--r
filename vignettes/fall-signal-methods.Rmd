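---
title: "Methods: disproportionality and rule mining for fall-related adverse events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and rule mining for fall-related adverse events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallsignal)
```

## The problem

Spontaneous-reporting-system (SRS) databases collect voluntarily
submitted adverse-event reports. They have no denominator population and
heavy reporting biases, so absolute risks cannot be estimated; what can
be estimated is *disproportionality* — whether a drug class is reported
together with a target event more often than the database background —
and *co-occurrence structure* — which combinations of patient and drug
attributes accompany the event. `fallsignal` implements both for
fall-related events (falls, dizziness, orthostatic hypotension are the
default MedDRA Preferred Terms) over a four-table JADER-like schema:
demographics (DEMO), drugs with causality role codes (DRUG), events
(REAC), and comorbidity/primary-disease terms (HIST).

## Data model

A report is the join of the four tables on `report_id`. Reports are
stratified into nine 10-year age bands (≤19, 20–29, …, 80–89, ≥90).
Only descriptions carrying a usable integer — a plain age, an age with
the Japanese year suffix, or a decade form ("70s" → 70–79) — are banded;
categorical descriptions (young adults, adults, elderly, pregnancy
trimesters, unknown) are marked `EXCLUDED` because they cannot be placed
on the grid. `EXCLUDED` reports stay in the database and in the
full-database disproportionality analysis; only age-stratified rule
items and age subgroup analyses drop them. Ages ≥100 are folded into the
top band: the top band is open-ended (its decade-style display alias is
"90–99"), and we see no defensible reason to discard centenarian
reports.

Drugs are classified by **exact case-insensitive generic-name lookup**
(whitespace-trimmed) against a packaged 98-compound map of eight ATC
classes; no fuzzy matching, for determinism. Three entries of the
packaged table carry unusual spellings (triazoram, frosemide,
lefepramine); the standard spellings triazolam, furosemide and
lofepramine are accepted as aliases of the same entries. The five CNS
classes (opioids N02A*, benzodiazepines N05CD/N05CF, other hypnotics and
sedatives N05CA/N05CC/N05CH/N05CM, non-selective monoamine reuptake
inhibitors N06AA, SSRIs N06AB) form the composite *CNS-active* group of
the 2015 Beers Criteria. All three drug role codes (suspected,
concomitant, interacting) are included. Concomitant-drug counts are
counts of **distinct generic names**: a substance listed both as
suspected and concomitant counts once. This is the defensible reading of
"number of concomitant drugs" as a patient-level exposure; counting rows
would double-count re-listed substances.

## Reporting odds ratio

For a class, reports are cross-classified once each into the 2×2 table
(a = class & fall-related, b = class & other events, c = other drugs &
fall-related, d = other drugs & other events), and the crude ROR is
(a/c)/(b/d). The 95% CI is the Woolf log-normal interval
`exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))` — the SRS-literature standard,
and the construction that reproduces published fall-signal tables to
two decimals. A class is flagged a signal when the CI lower bound
exceeds 1 **and** a ≥ 2; the two-case minimum guards against single-report
artifacts. Zero cells make the log-scale CI undefined; we then apply the
Haldane–Anscombe correction (+0.5 to all four cells) and set a
`corrected` flag rather than failing or silently returning a finite
number. Displayed values are rounded to two decimals; all internal
computation is at full precision.

## Association rules

Each report becomes a transaction of namespaced items — `age:<band>`,
`n_cns:<k>` and `n_ccb:<k>` (only for k ≥ 1), `class:<name>`,
`hist:<term>`, and the consequent `ev:fall_related`. Reports with no
mapped items remain as empty transactions and still count toward the
transaction total D, which keeps supports interpretable as report-level
probabilities.

Frequent itemsets come from a level-wise apriori: candidates of size k
join two frequent (k−1)-sets sharing a (k−2)-prefix, are pruned when any
(k−1)-subset is infrequent, and are counted by intersecting sorted
transaction-id lists. "Frequent" means support ≥ min_support, i.e.
count ≥ ⌈min_support·D⌉ (at least 1); the inclusive ≥ reading is required
for the 3-case rules that published tables contain at min support 10⁻⁶.
`maxlen` bounds the total itemset size — antecedent plus consequent
jointly, the `arules` convention — so maxlen 3 allows up to two
antecedent items.

Rules with the fixed consequent are produced as a post-filter over
frequent itemsets containing it (equivalent to an appearance
constraint), keeping those with confidence ≥ min_confidence, and scored
with

* support = n(X∩Y)/D,
* confidence = n(X∩Y)/n(X),
* lift = confidence / (n(Y)/D),
* chi² = D·(lift−1)²·support·confidence /
  ((confidence−support)·(lift−confidence)),

with significance declared at chi² ≥ 4 (approximately p < 0.05 at 1 df).
The lift-based chi² expression is algebraically the Pearson chi-squared
of the rule's 2×2 table; the test suite verifies the identity
numerically to 10⁻⁶ relative error on random tables. Two boundary cases
need definitions: at exact independence (lift = 1) chi² is 0 by
definition, and when a denominator factor vanishes (antecedent or
consequent covering all of D, or no joint cases) chi² is returned as
`NA` with the reason in `chi_flag` instead of a spurious number. Output
is sorted by lift descending with deterministic tie-breaks (support
descending, then lexicographic antecedent) so that repeated runs are
byte-identical.

Age-subgroup runs (e.g. age ≥ 60 for the comorbidity analysis) mine the
subgroup's transactions; by default D is the subgroup size
(`support_denominator = "subset"`), but a `"full"` switch computes
support and lift against the full-database D, because published subgroup
tables are ambiguous about which denominator was used and the two
conventions differ by the subgroup fraction. Note that published
chi-squared columns for such subgroup tables are not internally
consistent with the formula above applied to their own printed
support/confidence/lift; we do not emulate that inconsistency.

## Synthetic databases

The simulator generates the structure the analysis assumes, with ground
truth known:

* independent Bernoulli exposure per class, default prevalence equal to
  each class's report share in a ~430k-report reference database
  (e.g. benzodiazepines ≈ 8.9%, calcium channel blockers ≈ 12%);
* given exposure to a CNS class, the number of distinct drugs drawn from
  that class follows `cns_count_dist` over 1..6 (default mass 0.70,
  0.20, 0.07, 0.02, 0.008, 0.002) — a count of 0 would contradict
  exposure, so the distribution starts at 1; calcium channel blockers
  analogously over 1..3;
* age-band probabilities chosen so that ≈57% of reports are at age ≥ 60,
  matching the reference database's elderly share; 2% of reports get a
  categorical (excluded) age description;
* comorbidity terms as independent Bernoulli draws at plausible SRS
  frequencies (hypertension 8%, diabetes 5%, depression 3%, dementia
  1.2%, herpes zoster 0.5%, …);
* the fall-related probability of a report is
  `clip(baseline · Π multipliers(items present))` with baseline
  3715/430587 ≈ 0.0086 — **multiplicative risk, not logistic**, because
  at rare event rates risk ratio ≈ odds ratio ≈ lift, which makes
  recovery tests directly interpretable: a planted multiplier m should
  reappear as ROR ≈ m and single-item lift ≈ m;
* filler drugs and filler events guarantee every report at least one
  drug and one event row; the same seed gives byte-identical output.

What the simulator does **not** emulate: reporting biases (notoriety
effects, stimulated reporting), duplicate reports, correlated
exposures (an optional shared-polypharmacy correlation was considered
and deferred — independent exposures are what the planted-recovery
arithmetic assumes), missing fields, or real-world drug-name noise.
Passing tests therefore demonstrate correctness of the statistical
machinery on data satisfying the model's assumptions, not robustness to
real SRS artifacts.

`fixture_from_counts(a, b, c, d, class)` builds a minimal database whose
2×2 table for the class is exactly (a,b,c,d); printed contingency tables
from the literature can thus be routed through the identical code path
as simulated data.

## Numerical and design choices

* Support threshold: inclusive (support ≥ min_support), count cutoff
  ⌈min_support·D − ε⌉ with ε = 10⁻⁹ guarding float error at exact
  multiples.
* Independence tolerance: |lift − 1| < 10⁻¹² treated as exact
  independence (chi² = 0).
* Woolf z = 1.96 fixed for 95% coverage; configurable via `conf_z`.
* Empty databases, empty transaction lists, all-zero contingency
  fixtures, and unknown classes/namespaces raise validation errors
  before any I/O; a failed pipeline stage removes its partial outputs.
* The pipeline itself is deterministic; its seed argument exists for
  future resampling extensions and for reproducibility bookkeeping.

## Problem sizes used in the validation suite

The test suite validates at sizes chosen to make Monte-Carlo error
negligible relative to the asserted tolerances while keeping the suite
quick to run: round-trip I/O at 10,000 reports; binomial calibration of
the null event rate at 50,000; planted-multiplier recovery (multiplier
2.0, prevalence 0.08, baseline 0.01) at 200,000 reports, where the
standard error of ln ROR is ≈0.06 so the asserted window [1.7, 2.3] is
±2 SD wide; monotone recovery across multipliers {1, 1.5, 2, 3} at
40,000; apriori versus exhaustive enumeration on 200 random databases of
up to 12 items and 200 transactions; and null calibration of the signal
criteria over 1,000 simulated null databases of 20,000 reports each,
where at most 5% of class tests may be flagged (the one-sided 2.5%
nominal rate plus the two-case filter leaves ample margin).

## Known limitations

* Name-based classification misses brand names, salts and spelling
  variants; an adapter for real PMDA headers and naming is a hook, not
  implemented.
* Crude RORs only: no stratified/adjusted RORs, PRR, IC/BCPNN or EBGM.
* MedDRA terms are opaque strings; no SOC/HLT hierarchy traversal.
* The chi-squared significance cutoff of 4 ignores multiplicity across
  rules, as is conventional for hypothesis-generating SRS mining; rule
  lists are exploratory, not confirmatory.
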