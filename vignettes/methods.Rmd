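---
title: "Screening claims for drug–drug interactions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening claims for drug-drug interactions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiscreen)
```

## The screening model

A *potential* drug–drug interaction (pDDI) is a co-prescribed pair listed
in a severity-graded compendium — a flag for review, not an observed
adverse event. The unit of screening is the prescription: all distinct
matched systemic drug concepts it contains are paired (unordered,
alphabetically keyed on normalized names so A–B ≡ B–A), and each pair is
looked up in the knowledge base. Severity forms a total order,
contraindicated > major > moderate; when a source lists one pair at
several grades, the maximum is retained, and *minor* rows are dropped at
ingestion — with a counter, so they can never leak into a denominator.

Key counting rules, each of which changes the numbers if varied:

* a pair is counted **once per prescription**, regardless of duplicated
  line items (duplicates would otherwise fabricate self-pairs and inflate
  pair frequencies);
* **unmatched** free-text names are retained as inert items: they count
  toward the drug count (polypharmacy is a fact about the prescription)
  but cannot interact (interactions are defined only against the
  reference list);
* **non-systemic** items (a formulation keyword — cream, lotion, drops,
  ointment, gel, topical, shampoo — as a whole token) are removed at the
  line-item level *before* the single-drug exclusion test. We read the
  alternative — dropping any prescription containing one topical — as
  inconsistent with sensible cohort accounting (a 6-drug prescription with
  one eye drop would vanish entirely); both behaviours are implemented and
  the whole-prescription variant is a `topical_removal` switch, as is
  applying the single-drug test before topical removal;
* a matched topical of a reference-list drug does **not** satisfy the
  "contains a reference drug" inclusion rule (it cannot contribute an
  interaction, so it should not admit a prescription into the screened
  denominator).

The exclusion cascade (missing sex or age → fewer than two drugs → no
reference-list drug) uses first-match accounting: a prescription missing
both sex and a second drug lands in the demographics bucket only. The four
buckets are therefore disjoint and sum exactly to the input count — a
property fuzz-tested in the suite.

## Severity profiles

Each prescription is assigned one of eight mutually exclusive categories
determined solely by the *set* of severities present: none, moderate-only,
major-only, contraindicated-only, moderate+major, major+contraindicated,
moderate+contraindicated, all three. The categories partition the cohort;
the "none" share is exactly the complement of prescription-level
prevalence. Instance-level severity shares are undefined (reported absent,
not zero) when no interactions were detected.

## Statistical summaries

All percentages are computed at full precision and displayed rounded
half-away-from-zero to two decimals; rounding is display-only. Stratified
tables (sex, age group 0–18/19–39/40–64/65–100 as closed integer
intervals, top-10 specialties by volume) attach a χ² test on proportions
and, for interaction-count means, Student's t (two strata) or one-way
ANOVA (more), gated by a Shapiro–Wilk normality pre-check on a subsample
capped at 5,000 (the test degenerates at claims scale); when the gate
rejects, the rank-based analogue (Wilcoxon / Kruskal–Wallis) is used.
p-values are kept exact internally and displayed with a `<0.001` floor. No
multiple-testing correction is applied. The pair-coverage denominator is
the loaded knowledge base's pair count rather than C(n,2): with
combination products as first-class concepts the pair universe is a
property of the KB, not a formula.

Two "mean interactions per prescription" variants are computed and
labelled — over all prescriptions and over interacting prescriptions only —
because both denominators are in common use and silently switching between
them is a classic reporting trap.

## Regression models

The per-prescription interaction count is modelled by **ordinary least
squares** on drug count, age group, sex, and specialty (references: 0–18,
male, general practice; specialties under 5,000 prescriptions dropped with
accounting). A linear model for a count is a deliberate choice — the
robustness mechanism for assumption violations is the **case-resampling
bootstrap** (default B = 1,000, percentile 2.5/97.5 CIs, seed-reproducible;
a resample losing a factor level is redrawn and counted, capped at 10·B),
not a Poisson likelihood; Poisson/negative-binomial variants are noted
extensions, out of scope. The interaction-adjusted model adds
`drug_count ×` category product terms, so the drug-count coefficient is
the slope at the reference levels and each product term is that group's
slope increment. Presence of a contraindicated pair is modelled by
logistic regression with Wald CIs on the log-odds scale, reported as odds
ratios with the model AIC.

Collinearity is diagnosed with VIF_j = 1/(1−R²_j) from regressing
model-matrix column j on the others, flagged at ≥ 3; an aliased column is
reported as `Inf` rather than a large finite number. The implementation
(auxiliary regressions via `lm.fit`) is tested against an independent
oracle (the diagonal of the inverse correlation matrix) to 1e−8.

Standard errors treat prescriptions as independent; with ~2.4
prescriptions per patient this understates uncertainty slightly, and a
clustered or mixed-effects variant is a known limitation, not implemented.
Both analytic and bootstrap CIs are emitted when the bootstrap runs.

## The synthetic world

The generator's defaults are a single stated world, fixed once:

* ~2.41 prescriptions/patient and ~4.86 ± 2.43 drugs/prescription with
  ~47.5% polypharmacy. A Poisson cannot produce that variance at that
  mean, so drug counts are **shifted negative binomial** (1 + NB,
  truncated ≥ 1, dispersion 7.3) with the NB mean calibrated by root
  finding so P(count ≥ 5) hits the polypharmacy target exactly;
* age mixture (13.8/19.8/43.0/23.4% across the four groups), 58% female,
  13 specialties with general practice at 42% of volume;
* knowledge-base severity densities (0.4% contraindicated, 4.7% major,
  2.5% moderate of all concept pairs) derived once from the reported
  world: ~46% prescription prevalence at ~5 drugs/prescription implies
  roughly 7% of pairs interacting, split to mirror the observed ~63/33/5
  instance shares;
* claims-style roughness: 30% brand-alias substitution, dose/form
  decoration, 5% injected topical items, 2% unknown names, 1.16% missing
  demographics;
* specialty formularies are Dirichlet-perturbed preference vectors over a
  Zipf-like popularity law, so specialty-level heterogeneity in
  interaction burden exists and can be modelled.

Every cohort ships a truth record: planted concepts per item, the expected
exclusion bucket per prescription, and per-prescription interactions
computed by a brute-force double-loop oracle that shares no code with the
join-based screening path. Model-truth data draw outcomes directly from
stated coefficients (linear predictor + Gaussian noise, or
Bernoulli-logistic), so parameter-recovery and CI-coverage tests have an
unambiguous target.

What a green test establishes: the pipeline's arithmetic, counting rules,
and estimators are correct *for data with this structure*. What it does
not: that real claims share the generator's independence assumptions — real
prescriptions correlate drugs through indications (co-morbidity patterns,
protocol pairs like dual antiplatelets), real alias tables are incomplete,
and real severity assignments drift between compendium versions. Headline
prevalence from synthetic runs is a property of the configured world, not
an estimate of any country's burden.

## Numerical choices and degenerate inputs

* Pair keys: names are trimmed, whitespace-collapsed, case-folded;
  alphabetical order is defined on that normalized form. Self-pairs are a
  distinct error (`duplicate_drug`), never "absent".
* Alias matching: case-insensitive substring containment,
  longest-pattern-first, ties broken by canonical-name order; matching is
  invariant to concept-table row order. A pattern claimed by two concepts
  is a build-time error, not a precedence guess.
* Combination products are concepts in their own right (no decomposition
  into components); their KB rows stand alone.
* Ages above 100 map into 65–100 with a warning counter; negative ages are
  errors. The 18/19 boundary follows from closed-interval group labels.
* A constant outcome gives slopes of exactly zero and adjusted R² reported
  as 0 (the 0/0 ratio is defined away rather than propagated as NaN).
* Quasi-separation in the logistic model is detected by coefficient/SE
  blow-up and reported as an error naming the term, because silently huge
  ORs are worse than a refusal.
* Network exports recompute node totals over *retained* edges after top-k
  truncation, so node size and visible edges always agree; exports are
  byte-stable and GraphML round-trips to identity. The top-k for the
  network stage has **no default** — it is a required parameter, since any
  default would silently shape the figure.

## Known limitations

No dates, durations, adherence, or cross-prescription (patient-temporal)
interaction logic; no ATC mapping or fuzzy name matching; no
pharmacokinetic mechanism annotation; no clustered standard errors; no
attempt to reproduce any real cohort's exact counts, which would require
the non-shareable source data.
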