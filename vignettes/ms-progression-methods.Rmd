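---
title: "Methods: the 12-state Markov model of metabolic syndrome progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 12-state Markov model of metabolic syndrome progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msprog)
```

## The model

Metabolic syndrome (MS) under the CDS 2004 criteria is the co-occurrence of
at least three of four components: overweight/obesity, hypertension,
dyslipidemia and hyperglycemia. The 16 possible component profiles are
collapsed into 12 mutually exclusive, collectively exhaustive states — no
component, four isolated states, six pair states and MS (which pools the
five profiles with ≥ 3 components). The four post-MS 3-component states are
deliberately not distinguished: the model describes progression *up to* the
syndrome, and the MS state absorbs all higher-order profiles.

Progression is modelled as a discrete-time Markov chain with a 1-year
cycle, separately in four strata (men and women, baseline age 18–49 and
≥ 50). Two assumptions carry the whole construction:

1. **Markov property** — the state next year depends only on the current
   state, not on the path taken to reach it;
2. **Time homogeneity** — the annual transition matrix is constant over the
   follow-up period (and over the 10-year projection horizon).

Neither is innocuous for a lifestyle-driven syndrome: medication uptake,
ageing within a stratum and secular trends all violate homogeneity to some
degree. The stratification by sex and coarse age band is the model's only
concession to covariates.

## Classification

`diagnose_components()` applies the cut-offs with the printed inequality
directions: `>=` for BMI (25.0 kg/m²), SBP (140 mmHg), DBP (90 mmHg), TG
(1.7 mmol/L), FPG (6.1 mmol/L) and 2-h post-meal glucose (7.8 mmol/L), and
strict `<` for HDL-C (0.9 mmol/L in men, 1.0 in women). Boundary behaviour
is load-bearing — a woman with HDL-C exactly 1.0 is *not* dyslipidemic — and
is pinned by dedicated tests. Each medication flag substitutes only for its
own component. The 2-h glucose is optional: routine check-ups rarely
measure it, and when absent hyperglycemia is decided from FPG and
medication alone. When height and weight are present, BMI is recomputed as
weight/height² and preferred over a supplied BMI field that disagrees by
more than 0.1 kg/m² (the discrepancy count is messaged).

## Cohort construction

Eligibility mirrors the standard check-up cohort design: baseline age 18–88,
no coronary heart disease, type I diabetes or familial hyperlipidemia, no
missing or physiologically impossible required fields at any visit (BMI ≤ 0,
SBP ≤ DBP or negative lab values count as missing information), and at least
two visits in consecutive calendar years. Each excluded subject is reported
under the *first* triggering reason in the fixed priority order age →
disease → missing information → no consecutive visits; the order is a
reporting convention chosen for determinism, since only a combined excluded
count is ever published for such cohorts.

A subject's stratum is fixed at baseline age and never updated, even when
follow-up crosses 50: the estimator stratifies subjects, not person-years.
Transition pairs are adjacent same-subject visits exactly one year apart;
a gap year contributes nothing (no interval-censoring machinery — a
deliberate non-goal). The cycle index of a pair is its from-year minus the
window start year plus 1, so the default 2010–2015 window yields five
cycles.

## Estimation

For stratum *s* and cycle *c*, the per-cycle matrix entry is the observed
proportion n~ij~(c)/n~i·~(c). The annual matrix is the arithmetic mean of
each row over the cycles in which it is defined. Two degenerate cases need
policy:

* **Zero-denominator rows** (no pairs left state *i* in cycle *c*) are
  treated as *undefined*, not zero, and excluded from the mean. Averaging
  zeros would bias every estimate toward 0 and destroy row-stochasticity.
* **Never-observed rows** are completed as the identity row (self-retention
  1) and flagged in `identity_rows`: a usable matrix is needed for
  propagation, and pure self-retention is the least-assumptive completion.
  Flagged rows are excluded from parameter-recovery error summaries.

After averaging, each row is renormalized to sum to exactly 1; the
pre-normalization deviation (zero up to floating point when every cycle row
is complete) is retained as an attribute. Estimation keeps full floating
precision throughout; rounding to two decimals happens only in reporting.

## The published matrices

The four published matrices ship as JSON fixtures carrying the printed
two-decimal percent entries plus per-row checksums. Loading validates every
row sum against 100 ± 0.05 (printed rows sum to 99.98–100.02), converts to
proportions and renormalizes. One cell of the men-18–49 matrix is printed
corrupted ("0.6.24" in the isolated-hyperglycemia row). The fixture resolves
it as 6.24% in the `OW_HYP` column because (a) the row then sums to 99.99
and (b) the analogous hyperglycemia → overweight+hyperglycemia cell is
nonzero in the other strata; the row-sum argument alone cannot distinguish
6.24 from 6.25, nor strictly rule out the `OW_DYS` column, so
`printed_matrix(..., hyperglycemia_cell = "OW_DYS")` exposes the alternate
reading. The resolution lives in exactly one fixture file.

## Prediction semantics

`predict_risk()` propagates a point mass: occupancy(t) = occupancy(t−1) · P.
Year 0 is the deterministic start; year 1 equals the matrix row, matching
the convention that first-year predictive rates *are* the transition
probabilities. Two candidate definitions of "risk of MS at year t" coexist:

* **occupancy** — P(in MS at year t) under the full reversible matrix
  (the published matrices contain exits from MS, e.g. 24.75% of men 18–49
  leave MS within a year);
* **cumulative incidence** — P(ever entered MS by year t), computed with
  the MS row made absorbing.

The package computes both, but treats occupancy as the primary "predictive
rate", a choice resolved empirically: five-fold propagation of the
published men/women 18–49 matrices from the no-component state gives
occupancies of 18.10% and 5.14%, against published 5-year estimates of
18.22% and 5.33%, whereas the absorbing variant gives 24.27% and 8.38%.
The residual ~0.1–0.2-point gap is consistent with propagating matrices
known only to two printed decimals (the prediction is a degree-5 polynomial
in 144 rounded entries, and the published projections were computed from
full-precision estimates); the acceptance test therefore asserts agreement
within 0.25 percentage points rather than at printed precision.

One published ordering claim does not survive contact with the published
numbers themselves: across the four matrices, the 10-year predictive rate
from isolated hyperglycemia exceeds every other isolated start, and
hyperglycemia-containing pair starts exceed the others in three strata —
but for men 18–49 the `DYS_HYP` start (41.83%) sits *below* the `OW_HTN`
start (42.29%), whose matrix row carries an unusually large direct
transition to MS (23.91%). The corresponding expectation in the acceptance
suite is left failing by design; it documents a property of the printed
matrix, not an implementation defect.

## The synthetic cohort generator

Because no check-up data are distributable, every pipeline stage is
exercised on generated cohorts (`simulate_cohort()`). The generator
emulates the structural features the estimator relies on:

* staggered entry, uniform over calendar years 2010–2014;
* geometric follow-up attrition, capped at 2015. The default dropout of
  0.25/year gives a mean of ≈ 3.0 visits per subject, matching the
  follow-up intensity typical of check-up cohorts of this design (total
  person-years ≈ 3 × subjects);
* stratum-specific Markov dynamics, defaulting to the four published
  matrices, with a uniform baseline state distribution (configurable,
  e.g. to observed baseline prevalences);
* a measurement model that *inverts the classifier*: each component flag is
  rendered by sampling on the correct side of every cut-off, on grids at
  measurement precision (BMI 0.1 kg/m², blood pressure 1 mmHg, labs
  0.01 mmol/L). Hypertension/hyperglycemia positives arise via the
  medication flag with probability 0.2, measured hyperglycemia via 2-h
  glucose (with normal FPG) with probability 0.1. A configurable exclusion
  margin around each cut-off defaults to 0 so that boundary values on the
  legal side are generated — boundary behaviour is where classification
  bugs live. MS visits sample one of the five admissible ≥ 3-component
  profiles uniformly. The round-trip guarantee (classifier ∘ renderer =
  identity on states) is exact by construction and property-tested;
* planted ineligible subjects (disease flags, missing fields, age
  outliers) at configurable counts, to verify the filter removes exactly
  them.

What it does **not** emulate: correlated physiology within a state (BMI,
blood pressure and lipids are sampled independently given the flags),
within-subject measurement autocorrelation beyond the state chain,
informative dropout, and secular trends. Sequences are independent across
subjects given the stratum matrix — exactly the model's own assumptions.
Passing recovery tests therefore show the *pipeline* is consistent (the
estimator recovers the generating dynamics), not that the Markov
assumptions hold in real populations. The spec's seed fully determines the
output; two runs with the same spec are byte-identical.

## Numerical choices and problem sizes

* Row-stochasticity is enforced at 1e-9 throughout (estimation, fixture
  loading, propagation input validation).
* Fixture row sums are accepted within ± 0.05 percent of 100 — half a unit
  in the last printed digit per 12-entry row.
* Chi-square tests are uncorrected Pearson on the 2×k table (df = k−1);
  a zero expected cell raises an error rather than returning NaN.
  P-values below 1e-4 are formatted "< 0.0001".
* The parameter-recovery experiment in the test suite uses 50,000 subjects
  per stratum (≈ 80,000 transition pairs per stratum, ≈ 10 s end-to-end),
  and the consistency check compares maximum absolute error at 800 vs
  6,400 subjects. With the study-design defaults the worst per-entry
  binomial standard error of the five-cycle mean estimator is ≈ 0.006, so
  the maximum error over the ≈ 320 defined entries concentrates around
  0.015–0.02: the suite asserts every entry within 4 binomial standard
  errors of its realized denominators, alongside a nominal absolute bound
  of 0.02 whose single-entry exceedances at the third decimal are expected
  sampling behaviour, not estimator bias.

## Limitations

The model inherits the design's constraints: transition probabilities are
assumed constant over follow-up and projection; strata are fixed at
baseline even when subjects age across 50; gap years are discarded rather
than interval-censored; no confidence intervals accompany the transition
probabilities or projections (none are published to compare against, and
bootstrap machinery is out of scope); and the descriptive layer reports
chi-square tests only for categorical rows. The alternative syndrome
definitions (NCEP-ATP III, IDF, harmonized) and waist-circumference-based
obesity are out of scope by design.
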