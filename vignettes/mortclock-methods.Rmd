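---
title: "mortclock: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mortclock: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package models

`mortclock` implements a complete pipeline for building and auditing a
*digital aging clock*: a model that predicts one-year all-cause mortality
for every person in an administrative registry from their longitudinal
coded history (diagnoses, procedures, drug purchases, primary-care and
socioeconomic records) plus fixed demographic attributes. The score is a
probability of death within a one-year predictive interval; its
discrimination beyond chronological age is what makes it interesting as an
aging marker, and its behaviour across sensitive groups is what the
fairness module audits.

Real national registries of this kind are permit-restricted. The package
therefore ships a synthetic-registry simulator as a first-class module: all
tests, demos and audits run against worlds whose generating process is
known exactly, which turns every downstream claim (coefficient recovery,
model ordering, planted unfairness detection) into a closed-loop check.

## The synthetic registry

### Population

Persons carry a birth date (uniform over a configurable range, default
1925-2005), sex (female with probability 0.508), a 10-level categorical
region with Zipf-decaying shares, marital status, immigration and
mental-health-diagnosis flags, an old-age pension (log-normal, defined for
persons 65+ at the reference date), a latent standard-normal frailty, and
optionally an emigration date predating every predictive interval. All
attributes are drawn independently of frailty, so in the unbiased world the
sensitive attributes carry no mortality information — the null case every
fairness false-positive check relies on.

### Events

Five record categories mimic a Nordic register stack with their historical
start years: socioeconomic records from 1970, drug purchases from 1995,
secondary (outpatient/hospital) diagnoses and surgical procedures from
1998, primary care from 2011. Counts per person, category and calendar
year are Poisson with

log lambda = log(base_rate) + alpha_c (age - 40)/10 + gamma_evt * frailty,

the frailty loading applying to medical categories only. Codes are drawn
Zipf(s = 1.1) over each category's vocabulary, so a minority of codes
carries most volume, as in real coded data. The event-frailty loading
(default 0.65) is a deliberate, documented signal channel: frail people
really do touch the healthcare system more, and a sequence model can and
should exploit record density. No category emits records before its start
year, and registers stop at death and at emigration.

### Mortality

The annual death hazard is discrete-time logistic:

logit h = beta0 + beta_age (age-70)/10 + beta_sex [male] + gamma * frailty
          + sum_k w_k exp(-dt_k / tau),

where dt_k is the time since the most recent occurrence of planted *risk
code* k (six mid-frequency codes spread over the medical categories,
weights 3.0 down to 1.2, tau = 1.5 years). The logistic-with-exponential-recency
form is invented, chosen precisely because a maximum-likelihood refit of
the same form on simulated data is a closed-loop recovery test for every
coefficient.

Two numbers were *calibrated once and frozen* rather than chosen freely:

* `beta0 = -6.62` was set by Monte-Carlo search so the default world's
  case fraction in a predictive year matches the anchor of 1.02 cases per
  100 controls (about 1.01% of those alive at the year's start). The
  calibration is part of the stated world; the acceptance suite verifies
  it at n = 100,000 within 3 binomial standard deviations.
* The risk-code weights, the recency decay tau and the event-frailty
  loading were scaled jointly so that two properties the package asserts
  of its own default world actually hold. First, the *observable* oracle
  (the true hazard with the unobservable frailty term removed) beats the
  age+sex baseline by about 0.08 AUC — with a weaker planting the
  required model ordering (recurrent model ahead of the baseline by at
  least 0.03 AUC at n = 20,000, where the test split holds only ~40
  deaths) would be unattainable by *any* trainable model. Second, the
  recency decay is sharp (tau = 1.5 years), so 50% record thinning
  measurably degrades *within-group* discrimination: presence-style and
  count-style signals are nearly invariant to uniform thinning (thinning
  scales every group member's counts alike, preserving their ranking),
  so without a sharp recency channel the planted observation bias would
  be statistically undetectable and the fairness audit would have
  nothing to find.

Deaths are emitted to two registers: source B always carries the full
date; source A carries the year only, correct with probability 0.9983 and
perturbed by one year otherwise — reproducing the near-but-not-total
agreement of real dual death registers. A generic cause-of-death label
(`cod_01..cod_20`) is drawn, tilted toward the strongest recent risk code.
Death weeks live on a 1..52 grid (`ceiling(day-of-year / 7)` capped).

### Planted observation bias

`apply_observation_bias()` drops each *medical* record of a disadvantaged
person independently with probability delta (default 0.5). Outcomes and
fixed attributes are untouched: the planted unfairness mechanism is
reduced observation, not altered risk — the leading hypothesis for why
clinical prediction models underperform for disadvantaged groups.

## Cohorts: prospective, temporally shifted

The population splits 70/10/20 at person level (largest-remainder
apportionment, seeded permutation). Each split has its own one-year
predictive interval — train 2018, validation 2019, test 2020 — so later
splits' outcome periods are unseen during training, and features are
usable only up to a cutoff 3 months before each interval (the buffer
prevents outcome leakage; last usable day is Sep 30). Exclusions, in
order: dead before the interval (union over both death registers),
emigrated before it, or zero records of any kind ever. Outcome labels are
the union of the two death sources; event weeks come from the full-date
source, with week 26 imputed for year-only cases (the label is unaffected;
only survival analyses see the imputation). A death date equal to the
interval start is included (closed interval start).

## Sequence encoding

Age is the timescale: one row per age year from birth to the feature
cutoff. A row holds the *distinct* vocabulary indices of that year's codes
(0 = PAD, 1 = UNK for codes unseen in training); rows with more than 100
distinct codes are reduced to a seeded uniform subsample of exactly 100,
drawn once at encoding time so that all downstream metrics are
reproducible; the subsample seed derives from (person, age-year) so
single-person and whole-cohort encoding agree entry for entry. Empty age
years are kept as PAD rows — the recurrent layer sees elapsed time through
the accompanying standardized age sequence. Fixed features are standardized
(continuous), mode-imputed with missingness flags (ordinal), or one-hot
with an explicit MISSING level (categorical); all statistics come from the
training split only. Standardized age-at-index is included among fixed
features: it is demographic, always observed, and gives the output layer a
direct path to the strongest predictor.

## Models

The recurrent model follows the architecture contract: per age-year step,
the sum of the step's code embeddings concatenated with the standardized
age; one GRU layer (embedding and hidden size 250); dropout 0.46 on the
final hidden state; fixed features concatenated before a single affine +
logistic output. Training is Adam on mean binary cross-entropy, learning
rate 4e-4, weight decay 7.4e-6, batch size 200, early stopping on
validation AUC with best-epoch restore. Sum pooling within a year makes
within-year code order provably irrelevant, which the tests assert. Two
initialization choices matter under 1% prevalence and small cohorts: the
output bias starts at the training base rate (no epochs wasted re-deriving
the intercept), and the output-layer weights start at zero, so the score
contains only *learned* structure, never untrained-readout noise — without
this the best-validation epoch at demo scale is dominated by
initialization noise. The trainer is implemented in RcppArmadillo (single-precision,
fused-gate GEMMs) because no deep-learning framework is available in the
target environment; at registry scale one would use a GPU framework, and
the contract (architecture, loss, optimizer, hyperparameters) is framework
agnostic.

**Training-schedule scaling.** At n = 20,000 persons a 70% training split
holds only ~150 cases, and the validation-AUC optimum sits at epoch 1-3;
longer schedules only overfit (training loss keeps falling while
validation AUC decays). The demo and acceptance runs therefore cap
max_epochs at 8 with patience 5. This is a runtime/cohort-size scaling of
the schedule, not of the printed optimizer hyperparameters, which are used
verbatim.

The baseline is an unregularized age+sex logistic regression (tiny-ridge
fallback under perfect separation, flagged). Comparators consume binary
code-presence vectors plus age and sex: penalized logistic regression
(glmnet; grid penalty {L1, L2} x C {0.001..100}, with scikit-learn's C
mapped to lambda = 1/(C n)) and gradient-boosted trees (own
histogram-based implementation; grid learning rate {0.01, 0.05, 0.1} x
depth {3, 5, 7} x row subsample {0.5, 0.75, 1} x feature subsample
{0.5, 0.75, 1} x rounds {50, 100, 150}), both selected by mean 3-fold CV
AUC and refit on the full training split.

## Evaluation

AUC is Mann-Whitney with half-credit ties; AUPRC is step-interpolated;
Brier is the mean squared error between score and label. Bootstrap 95%
CIs use 1,000 pair resamples and the 2.5th/97.5th percentiles
(single-class resamples are redrawn and counted). The AUC-difference test
permutes group membership of the pooled records, with the one-sided
p-value (1 + #{perm >= obs}) / (B + 1) as the default and a two-sided
flag; subgroups need at least 5 in their minority class or the result is
an explicit skip status.

Calibration bins scores either with equal sample counts (default) or
equal case counts. The two strategies are both implemented because the
source material describes both in different places; the conflict is
resolved by making the strategy an explicit argument rather than by
picking silently.

Survival machinery runs on the 1..52 week grid. The C-index is Harrell's
over comparable pairs. The time-dependent AUC is the cumulative/dynamic
variant; a subject censored at exactly week t counts as a control at t,
because on this grid censoring at week t means observed event-free through
week t — this convention makes t = 52 coincide exactly with the binary
AUC under administrative censoring, which the tests assert. Kaplan-Meier
bands use the exponential-Greenwood (log(-log)) transform and are verified
against `survival::survfit(conf.type = "log-log")`. Risk groups cut
percentile ranks (average ties) at 90 and 95.

## Fairness audit

Two subgroup AUC notions are kept strictly apart: *identification*
(subgroup cases against all controls — how visible the subgroup's deaths
are population-wide) and *differentiation* (cases and controls from the
subgroup only — discrimination after subgroup membership is conditioned
away). For the age+sex baseline, differentiation inside a single
(age-year, sex) stratum is exactly 0.5 — the score is constant there — a
property the tests assert because it explains why baseline rows go flat
when age is conditioned away.

Continuous attributes are binned with equal case counts per bin. The
classification threshold maximizes the geometric mean of sensitivity and
specificity over all observed cutpoints (ties to the lowest threshold).
Age-sex matching downsamples the larger arm within each exact
(age-year, sex) stratum. The intersectional report dichotomizes pension at
the case-equalizing cut (the median pension *among cases*, equalizing case
counts in the two pension groups rather than person counts), computes
per-attribute differentiation AUCs with one-sided permutation p-values
(advantaged minus disadvantaged), AUC by count of simultaneous
disadvantages, and all 2^4 intersection sizes. For multi-level attributes
(region), each level is tested against the pooled complement. Adjusted
record counts regress per-person totals on age and sex and z-normalize
the residuals before averaging per bin.

## Explainability

Players are distinct codes (all occurrences of a code toggle together);
the baseline is the person with *no* longitudinal codes (all rows PAD,
ages kept); a coalition's value is the model probability after deleting
non-member codes from every row. Deletion (compact + re-pad), not
UNK-substitution: the stated baseline is the absence of longitudinal
information, not corrupted information. Exact Shapley enumerates all 2^n
coalitions for n <= 12 and is additive to numerical precision; the
sampled estimator averages marginal contributions over random player
permutations (unbiased; per-player Monte-Carlo standard errors; coalition
values cached). Population aggregates use a configurable person fraction
(default 6.5%) and report mean |phi| by category, by years before the
index date (a player's most recent occurrence year), or by training
prevalence bin. The last-5-years exclusion analysis is served by
re-encoding with the cutoff shifted five years earlier, not by ad-hoc
masking. Category permutation importance swaps each person's
out-of-category history with that of a random donor (aligned by age year)
and reports the retained AUC.

## What a green test establishes — and what it does not

The simulator produces the statistical *structure* the pipeline assumes:
register start years, dual death sources with realistic agreement,
age/sex/frailty-driven hazards, code recency effects, and
disadvantage-dependent completeness. It does not emulate real code
vocabularies, competing risks, family linkage, geography beyond a
categorical label, or care-pathway correlations between codes. A green
acceptance suite therefore establishes that the machinery is correct and
that planted effects of realistic size are recovered — not that the
paper-scale headline numbers would be reproduced on the real registry,
which is expressly out of reach.

## Numerical and degenerate-input choices

Zero-variance continuous features standardize with SD 1 plus a warning;
all-missing features impute 0 with a permanently set missingness flag.
Unknown categorical levels at inference map to MISSING with a warning;
unseen codes map to UNK rather than being dropped, preserving sequence
density. Constant scores produce a warning and an all-low risk grouping.
Bootstrap intervals are reported as percentile pairs; the point estimate
is not asserted to lie inside (percentile intervals may exclude it in
pathological cases). All randomness flows through explicit seeds; a
documented integer hash fans the pipeline's global seed out to per-stage
seeds.
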