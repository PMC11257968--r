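# mortclock

Digital short-term mortality clocks from longitudinal registry data —
simulation, modelling, evaluation, fairness auditing and explainability in
one package.

## The problem

Short-term (one-year) mortality risk is a practical proxy for biological
age: a model that separates people who will die within a year from those
who will not, *beyond what chronological age already explains*, captures
frailty. Nationwide administrative registries — coded diagnoses,
procedures, drug purchases, primary-care contacts and socioeconomic
records spanning decades — are rich enough to build such a "digital aging
clock", but they are permit-restricted, and models trained on them raise
algorithmic-fairness questions: does the score work equally well for
unmarried, immigrant, mentally ill or low-pension individuals, whose
records may be systematically thinner?

`mortclock` implements the complete pipeline against a bundled
synthetic-registry simulator whose generating process is known exactly:

* **synthetic registry** — persons, five event categories with historical
  register start years (socioeconomic 1970, drug purchases 1995,
  secondary care 1998, primary care 2011), a discrete-time death hazard
  `logit h = beta0 + beta_age (age-70)/10 + beta_sex [male] +
  gamma f + sum_k w_k exp(-dt_k/tau)` with latent frailty `f` and planted
  risk codes, dual death registers with 99.83% agreement, and planted
  disadvantage-dependent record dropout;
* **cohorts** — prospective temporally-shifted 70/10/20 splits (train
  2018, validation 2019, test 2020) with a 3-month pre-interval buffer,
  inclusion/exclusion, and outcome labels from the union of both death
  sources;
* **encoding** — age-year code sequences (distinct codes per age year,
  100-entry row cap, PAD/UNK) plus standardized fixed features, and binary
  presence vectors for comparators;
* **models** — a GRU sequence model (embedding/hidden 250, dropout 0.46,
  Adam lr 4e-4, weight decay 7.4e-6, batch 200; implemented in
  RcppArmadillo), an age+sex logistic baseline, penalized logistic and
  gradient-boosted-tree comparators with their full printed grids;
* **evaluation** — AUC/AUPRC with bootstrap CIs, permutation
  AUC-difference tests, Brier score, quantile calibration, Harrell's
  C-index, weekly time-dependent AUC, Kaplan-Meier risk groups with
  exponential-Greenwood bands;
* **fairness** — group identification vs differentiation AUCs, equal-case
  binning, geometric-mean thresholds with TPR/TNR decomposition, exact
  age-sex matching, intersectional disadvantage reports;
* **explainability** — exact and sampled Shapley attributions over
  longitudinal codes against a no-longitudinal-features baseline, category
  and prevalence aggregations, category permutation importance.

See `vignettes/mortclock-methods.Rmd` for the model, the generator's
calibration anchors and every numerical design choice.

## Worked example

```r
library(mortclock)

cfg  <- generator_config(n_persons = 20000)
reg  <- generate_population(cfg, seed = 1)
reg  <- simulate_events(reg, cfg, end_year = 2020, seed = 2)
reg  <- simulate_mortality(reg, cfg, horizon = 2018:2020, seed = 3)

spec <- split_spec()               # train 2018 / valid 2019 / test 2020
co   <- build_cohort(reg, spec, seed = 4)$cohort
st   <- fit_preprocessor(reg, co[split == "train", person_id],
                         spec$splits$train$feature_cutoff,
                         spec$splits$train$interval_start)
enc  <- lapply(c("train", "valid", "test"), function(s)
  encode_cohort(reg, co[split == s], st, spec$splits[[s]]$feature_cutoff,
                spec$splits[[s]]$interval_start, seed = 5))
names(enc) <- c("train", "valid", "test")

rnn  <- train_recurrent(enc$train, enc$valid,
                        recurrent_spec(max_epochs = 8, patience = 5),
                        seed = 6)
ptr  <- reg$persons[match(enc$train$person_id, person_id)]
base <- train_baseline(age_years(ptr$birth_date,
                                 spec$splits$train$interval_start),
                       ptr$sex, enc$train$label)

pte  <- reg$persons[match(enc$test$person_id, person_id)]
pred <- prediction_set(enc$test$person_id, enc$test$label,
                       predict(rnn, enc$test), enc$test$event_week,
                       attributes = data.frame(
                         age = age_years(pte$birth_date,
                                         spec$splits$test$interval_start),
                         sex = pte$sex))
evaluate_predictions(pred, B = 1000, seed = 7)
```

On this seed the run prints:

```
<eval_report> n=3796 (32 cases)
  AUC 0.9250 (0.8785-0.9633)  AUPRC 0.2274  Brier 0.00823  C-index 0.9233
```

Read: among the 3,796 test-split persons alive on 1 Jan 2020, the
recurrent clock ranks a random 2020 death above a random survivor 92.5% of
the time (the age+sex baseline on the same split reaches 0.8782); AUPRC is
low because prevalence is ~1%; the C-index is computed on the weekly
death-time grid. The same `pred` object feeds `disadvantage_report()`
(fairness) and `exact_shapley()` / `sampled_shapley()` (attribution).

The full pipeline — registry files, cohort files, model checkpoints,
evaluation/fairness/attribution reports and a hash manifest — runs from
one YAML config:

```sh
Rscript inst/cli/clock all --config inst/extdata/demo-config.yaml
```

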