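---
title: "Methods: cohort equalization, test selection and reporting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort equalization, test selection and reporting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohorteq)
```

## Scope and data model

`cohorteq` operates on one rectangular table of samples by variables. Two
columns carry roles: a unique identifier (never analysed, never imputed,
used only to address samples) and a target variable whose 2–15 distinct
values define the subpopulations being compared. Everything else is a
feature. Cells are text, numbers, or missing; on input the common missing
spellings (empty cell, `NA`, `NaN`, `N/A`, `null`, case-insensitively) are
collapsed to one marker. Numbers are parsed with a `.` decimal separator
only — a cell like `1,5` is treated as text, which demotes the column to
categorical rather than silently guessing a locale.

The 15-value cap appears twice, deliberately with the same constant: as
the maximum number of target subpopulations, and as the discreteness
threshold in type inference (a fully numeric column with at most 15
distinct values is treated as categorical). Low-cardinality numeric codes
— 0/1 flags, severity grades — are thereby analysed as the nominal
variables they are. The threshold is exposed as `max_categories` and can
be overridden per column, which is the escape hatch for a genuinely
continuous variable measured at few distinct levels.

## Imputation

Imputation happens once, before any statistics and before equalization, so
that every later step sees the same complete table. Rules per kind:

* **Categorical:** the mode, applied regardless of the missing fraction.
  Ties are broken toward the lexicographically smallest category — an
  arbitrary but deterministic rule, so re-runs are identical.
* **Continuous, missing fraction < 0.5 (strict):** Shapiro–Wilk on the
  observed values; `p > 0.05` selects the mean, anything else the median.
  The gate operationalizes "use the statistically appropriate location
  measure": the mean for a distribution it summarizes well, the median
  otherwise. With fewer than 3 observed values the test is undefined; the
  median is used and the record flagged.
* **Continuous, missing fraction ≥ 0.5:** left untouched and flagged. A
  variable that is mostly holes should be a conscious analyst decision,
  not a silent fill.

Model-based imputation (regression, multiple imputation) is deliberately
absent: single-value imputation keeps the audit trail simple — the report
logs variable, method, fill value and count — at the cost of shrinking
variance, which the report's flags make visible rather than hide.

## Test selection

The dispatch rule is the standard baseline-characteristics decision tree;
`select_test()` is a pure function of the variable kind, the group count,
the pooled normality verdict, and the expected contingency counts.

Numerical and procedural choices that needed fixing:

* **Yates continuity correction** is applied to every 2×2 chi-square. For
  2×2 tables with tiny observed-minus-expected deviations the corrected
  statistic collapses to 0 and p = 1, which is the behaviour clinicians
  see in published baseline tables.
* **Fisher fallback** triggers when any expected count in a 2×2 table is
  below 5 (the Cochran rule). For larger r×c tables with sparse expected
  counts the chi-square result is kept but flagged in the report; a
  general r×c exact test is out of scope.
* **Normality gate**: Shapiro–Wilk on the pooled non-missing values, with
  normal iff p > 0.05. The gate is pooled rather than per-group so that
  the same test is chosen for all groups. `shapiro.test()` accepts at most
  5000 values; beyond that the gate uses 5000 evenly spaced order
  statistics of the sorted sample — deterministic, seed-free, and shape-
  preserving.
* **Welch t-test** rather than pooled-variance: group variances are not
  assumed equal after subsampling, and with near-equal variances Welch
  reduces to the pooled test anyway.
* **Mann–Whitney U** uses the exact null distribution when the smaller
  group has ≤ 8 observations and there are no ties, otherwise the normal
  approximation with continuity and tie correction.
* **Kruskal–Wallis post hoc** is Dunn's z on mean ranks with the usual tie
  correction and Bonferroni adjustment — written in-package, as no
  installed library provides it, and verified in the tests against the
  textbook formula.
* **Display**: p-values print at 3 decimals, with values below 0.0005
  rendered `<0.001`; quantiles use linear interpolation (R type 7), and
  the IQR is reported both as its width and as the p25–p75 interval.

No multiple-testing correction is applied across variables: the report
mirrors the per-variable raw p-values of a baseline table, and says so.

## Impact scores

"How much does this variable separate the subpopulations?" is quantified
as summed total-variation distance from the pooled composition:
`impact(v) = Σ_g ½ Σ_c |p_g(c) − p̄(c)|`. The measure is bounded, zero
exactly at perfect balance, and indifferent to category order. Continuous
variables enter through quartile bins computed once from the pooled
distribution and held fixed while samples are removed; re-binning during
removal would make the objective a moving target. Missing cells form
their own bin, so per-group counts always sum to the group size and an
imbalanced missingness pattern is itself visible to the score.

## The three equalizers

All three remove whole samples, never reweight; all are driven by one
seeded generator (Mersenne–Twister, seed ≥ 1) with candidate identifiers
sorted lexicographically before any draw, so identical input and
configuration reproduce identical output byte for byte. Protected
identifiers are never removed. The kept/removed partition is verified
(`sanity_check()`) after every run.

**`equalize_samples`** downsamples each group uniformly at random to the
smallest group's size. If a group's protected samples alone exceed the
target it stays larger and the result is flagged.

**`equalize_proportions`** runs greedy steepest descent on total impact:
at each step every legal single-sample removal is scored and the best one
applied. Candidates exclude protected samples and — with `bypass = FALSE`
— any group whose *original* size was the minimum; removals also may not
invert the original size ordering of groups. Because removals within one
group and category are interchangeable, candidate evaluation runs per
(group × category-profile), not per sample, which keeps each step cheap.

The stopping rule deserves a note. Stopping the search at the first
moment every configured variable's test clears `p > alpha` sounds
attractive but parks the cohort exactly at the significance boundary (a
residual proportion gap of ~0.13 at 100 per group) — balanced in name
only, and unstable under re-testing. The implementation therefore runs to
a greedy optimum: it stops when no single removal strictly reduces total
impact (or at `max_iterations`), and then reports the p-based verdict in
the result's flags. A cohort that is already balanced admits no improving
removal, so nothing is removed.

**`advanced_equalize`** is the hybrid. Phase one computes impact scores,
processes variables in descending order, and removes — from oversized,
unprotected groups — the sample whose removal best moves the current
variable's group proportions toward the pooled proportions, sweeping until
every group sits at the smallest group's size. Phase two continues with
the same greedy impact descent as `equalize_proportions`, but across
*all* groups, including the smallest: this is what distinguishes the
hybrid, since proportion imbalance that survives size equalization can
only be fixed by trimming both sides. The `min_threshold` floor (default
5) is the safeguard: no removal may take a group at or below it any
lower, and a configuration whose threshold exceeds the smallest group is
rejected before any work is done. On the standard confounded cohort this
two-phase design recovers the confounder to a median absolute proportion
gap below 0.05 across seeds — size-phase-only designs plateau at ~0.25,
because the oversized group cannot shed enough of the over-represented
category while the exempt group keeps its composition.

Open choices resolved here, as this package's own design: removals are
single-sample greedy steps (not batched); the proportion target is the
pooled distribution of the currently kept samples (not the smallest
group's); default `alpha = 0.05`, `min_threshold = 5`,
`max_iterations = 10 ×` the sample count.

## Reporting and token estimation

The report is a plain-text, fixed-width document: dataset structure,
variable types, missingness quantification, the imputation log,
before/after descriptive summaries (counts and proportions; median, IQR
and p25–p75) with each variable's selected test and p-value, the
impact-score ranking, removed/surviving counts, per-category percentage
changes (`100 × (after − before) / before`, with categories absent before
flagged), the sanity-check verdict, processing time and the token
estimate. The numeric tables render in a pipe-aligned format that
`parse_report_tables()` reads back, so the report is machine-checkable;
the generation timestamp is the only non-deterministic line and can be
suppressed. The variable-type block describes the analysed (imputed)
table, while the missing-values block quantifies the raw input — the two
views are intentionally different.

The token estimate prices a table for language-model processing without a
tokenizer dependency: one word per cell, 1.333 tokens per word (the
1000-tokens-per-750-words guideline), over `n_rows × (n_columns − 1)`
cells. The identifier column is excluded because it would be stripped
before any model saw the data; rounding is half-up. The literal constant
1.333 matters: 4/3 would give 8400 where 1.333 gives 8398 on a 225×29
table.

## The synthetic cohort generator

`generate_cohort()` draws per-group: exact group sizes, categorical
features from per-group probability vectors, continuous features from a
location/scale family (normal, or a location-shifted exponential so the
non-normal branch of the gate is reachable), then punches missing cells
uniformly at random per feature. `standard_confounded_fixture()` fixes
the package's canonical test conditions: 150 cases vs 100 controls, a
binary confounder at 70% vs 30% prevalence, a balanced binary variable,
a continuous variable shifted by one pooled standard deviation
(N(67, 12) vs N(55, 12)), and 5% missingness per feature — a caricature
of a mid-sized observational case/control table.

What the generator does *not* emulate: correlated features, informative
(non-random) missingness, measurement error, longitudinal structure, or
heavy-tailed clinical mixtures. Tests passing on these cohorts therefore
demonstrate the algorithms' contracts (determinism, protection, partition,
impact reduction, confounder recovery), not robustness to every real-data
pathology.

Test problem sizes are kept modest by design — 250-sample cohorts for the
equalization properties, 20 seeds for the recovery property, 10,000 per
group only for the convergence check — enough for binomial sampling error
to be well inside the asserted tolerances.

## Known limitations

* Removal-based balancing discards data; the hybrid method in particular
  trades sample size for balance (130 of 250 survive in the README's
  example). Propensity or matching-weight approaches are out of scope.
* Greedy descent finds a local optimum; rare seeds can stall with a
  residual gap (the recovery property is therefore asserted on the median
  across seeds, not the maximum).
* The chi-square/Fisher asymptotic agreement is genuinely loose at
  moderate cell counts (differences up to ~0.07 near expected counts of
  50–100); this is a property of the tests themselves, not of the
  dispatcher.
* XLSX support covers the first worksheet of modern files (shared/inline
  strings, numeric cells); styled dates and formula-only cells are not
  interpreted beyond their cached values.
* The token estimate is a planning proxy, not a tokenizer: real token
  counts depend on cell content and model vocabulary.
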