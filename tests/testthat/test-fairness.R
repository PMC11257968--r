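make_pred <- function(n = 600, seed = 401, signal = 2.5) {
  set.seed(seed)
  age <- runif(n, 30, 95)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  risk <- plogis(-6 + 0.06 * age + 0.3 * (sex == "male"))
  y <- rbinom(n, 1, risk)
  score <- plogis(qlogis(risk) + rnorm(n) / signal)
  prediction_set(sprintf("p%04d", 1:n), y, score,
                 event_week = ifelse(y == 1, sample(1:52, n, TRUE), NA),
                 attributes = data.frame(age = age, sex = sex))
}

test_that("identification and differentiation AUCs agree with set oracles", {
  pred <- make_pred()
  mask <- pred$age > 70
  gi <- group_identification_auc(pred, mask)
  keep <- (pred$y == 1 & mask) | pred$y == 0
  expect_equal(gi$auc, auc_oracle(pred$y[keep], pred$score[keep]),
               tolerance = 1e-12)
  gd <- group_differentiation_auc(pred, mask)
  expect_equal(gd$auc, auc_oracle(pred$y[mask], pred$score[mask]),
               tolerance = 1e-12)

  # whole population: both modes equal the overall AUC
  all_mask <- rep(TRUE, nrow(pred))
  overall <- auc(pred$y, pred$score)
  expect_equal(group_identification_auc(pred, all_mask)$auc, overall)
  expect_equal(group_differentiation_auc(pred, all_mask)$auc, overall)

  # guard -> skip status, not an error
  few <- seq_len(nrow(pred)) <= 4
  expect_match(group_identification_auc(pred, few & pred$y == 1)$status,
               "skipped")

  # subgroup cases all top-ranked -> identification AUC 1
  pred2 <- copy(pred)
  top <- pred2$y == 1 & mask
  pred2$score[top] <- 0.99 + runif(sum(top)) / 100
  expect_equal(group_identification_auc(pred2, mask)$auc, 1.0)

  # constant score within subgroup -> differentiation 0.5
  pred3 <- copy(pred)
  pred3$score[mask] <- 0.4
  expect_equal(group_differentiation_auc(pred3, mask)$auc, 0.5)
})

test_that("baseline scores differentiate nothing within an age-sex stratum", {
  pred <- make_pred(2000, seed = 402)
  # scores that are a function of (age year, sex) only
  pred$score <- plogis(-5 + 0.05 * floor(pred$age) +
                         0.2 * (pred$sex == "male"))
  stratum <- floor(pred$age) == 75 & pred$sex == "male"
  if (sum(pred$y[stratum] == 1) >= 5 && sum(pred$y[stratum] == 0) >= 5) {
    expect_equal(group_differentiation_auc(pred, stratum)$auc, 0.5)
  }
  # narrow age bins: near 0.5
  bin <- pred$age >= 70 & pred$age < 75
  r <- group_differentiation_auc(pred, bin)
  if (r$status == "ok") expect_lt(abs(r$auc - 0.5), 0.15)
})

test_that("equal_case_bins: equal case counts, edge cases, quantile oracle", {
  set.seed(403)
  att <- rnorm(1000)
  y <- rbinom(1000, 1, 0.3)
  b <- equal_case_bins(att, y, 10)
  expect_equal(as.integer(table(b[y == 1])), rep(sum(y == 1) %/% 10, 10) +
                 (seq_len(10) <= sum(y == 1) %% 10))
  # oracle: sorted case attribute split into equal chunks
  cs <- sort(att[y == 1])
  sizes <- largest_remainder(length(cs), rep(0.1, 10))
  expect_equal(unname(cumsum(table(b[y == 1]))), cumsum(sizes))
  # all subjects assigned
  expect_true(all(b >= 1 & b <= 10))
  expect_error(equal_case_bins(att, rep(0, 1000), 10), "fewer cases")
  expect_error(equal_case_bins(rep(1, 100), rbinom(100, 1, 0.5), 5),
               "degenerate")
  # 100 cases, 10 bins -> exactly 10 per bin
  att2 <- runif(400)
  y2 <- c(rep(1, 100), rep(0, 300))
  expect_true(all(table(equal_case_bins(att2, y2, 10)[y2 == 1]) == 10))
})

test_that("gmean_threshold matches exhaustive scan; fixed-threshold tallies", {
  set.seed(404)
  for (rep in 1:5) {
    y <- rbinom(300, 1, 0.3)
    s <- round(runif(300), 2)
    got <- gmean_threshold(y, s)
    want <- gmean_oracle(y, s)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$gmean, want$gmean, tolerance = 1e-12)
  }
  # perfectly separated: gmean 1
  y2 <- rep(c(0, 1), each = 20)
  s2 <- c(runif(20, 0, 0.4), runif(20, 0.6, 1))
  expect_equal(gmean_threshold(y2, s2)$gmean, 1.0)
  expect_warning(gmean_threshold(c(0, 1), c(0.5, 0.5)), "constant")

  # metrics_at_threshold extremes and hand count
  y3 <- c(1, 1, 0, 0, 0)
  s3 <- c(0.9, 0.2, 0.8, 0.3, 0.1)
  m0 <- metrics_at_threshold(y3, s3, 0)
  expect_equal(c(m0$tpr, m0$tnr), c(1, 0))
  m9 <- metrics_at_threshold(y3, s3, 0.95)
  expect_equal(c(m9$tpr, m9$tnr), c(0, 1))
  mh <- metrics_at_threshold(y3, s3, 0.5)
  expect_equal(mh$tpr, 0.5)          # 1 of 2 cases at/above 0.5
  expect_equal(mh$tnr, 2 / 3)        # 2 of 3 controls below
  expect_equal(mh$accuracy, 3 / 5)
})

test_that("match_age_sex produces identical joint (age, sex) tables", {
  pred <- make_pred(1500, seed = 405)
  mask <- runif(nrow(pred)) < 0.4
  m <- match_age_sex(pred, mask, seed = 7)
  a <- m[m$.group == TRUE]
  b <- m[m$.group == FALSE]
  ta <- table(floor(a$age), a$sex)
  tb <- table(floor(b$age), b$sex)
  expect_equal(ta, tb)
  # already matched input comes back unchanged up to ordering
  m2 <- match_age_sex(m[, !".group"], m$.group, seed = 8)
  expect_equal(nrow(m2), nrow(m))
  # stratum present in only one arm is dropped
  pred2 <- rbind(pred, pred[1])
  pred2$age[nrow(pred2)] <- 120
  mask2 <- c(mask, TRUE)
  m3 <- match_age_sex(pred2, mask2, seed = 9)
  expect_false(any(floor(m3$age) == 120))
  expect_error(match_age_sex(pred[1:2], c(TRUE, TRUE)), "overlap|strata")
})

test_that("disadvantage_report: partition identity and null behaviour", {
  pred <- make_pred(1200, seed = 406)
  set.seed(406)
  pred$unmarried <- runif(1200) < 0.4
  pred$immigrant <- runif(1200) < 0.1
  pred$mental_health_dx <- runif(1200) < 0.2
  pred$pension <- exp(rnorm(1200, log(1800), 0.5))
  rep_ <- disadvantage_report(pred, B = 200, seed = 1)
  expect_equal(sum(rep_$intersections$n), nrow(pred))
  expect_equal(nrow(rep_$intersections), 16L)
  # pension cut equalizes cases across the two pension groups (+-1)
  low <- pred$pension < rep_$pension_cut
  expect_lte(abs(sum(pred$y[low]) - sum(pred$y[!low])), 1)
  expect_equal(nrow(rep_$attributes), 4L)
  # attributes independent of score/outcome: no tiny p expected systematically
  expect_true(all(rep_$attributes$p > 0.001, na.rm = TRUE))

  # all flags zero: single count-0 row equal to the overall AUC
  pred0 <- copy(pred)
  pred0$unmarried <- pred0$immigrant <- pred0$mental_health_dx <- FALSE
  pred0$pension <- NULL
  pred0$pension <- 1000  # constant: nobody strictly below the case cut
  rep0 <- disadvantage_report(pred0, B = 10, seed = 2)
  cnt0 <- rep0$by_count[rep0$by_count$n_disadvantages == 0, ]
  expect_equal(cnt0$n, 1200L)
  expect_equal(cnt0$auc, auc(pred0$y, pred0$score))
})

test_that("adjusted_record_counts: normalization identity and planted gradient", {
  world <- cached_world()
  reg <- world$reg
  iv <- world$spec$splits$test
  te <- world$cohort[split == "test"]
  pte <- reg$persons[match(te$person_id, person_id)]
  pred <- prediction_set(te$person_id, te$label, runif(nrow(te)),
                         attributes = data.frame(
                           age = age_years(pte$birth_date, iv$interval_start),
                           sex = pte$sex))
  bins <- sample(1:5, nrow(pred), replace = TRUE)
  tab <- adjusted_record_counts(reg, pred, bins, iv$feature_cutoff)
  allb <- tab[tab$category == "all", ]
  # bins independent of counts: means hover near 0
  expect_true(all(abs(allb$mean_adjusted) < 0.2))
  # plant a gradient: bin by (residualized) record count itself
  ev <- reg$events[person_id %in% pred$person_id &
                     event_date <= iv$feature_cutoff, .N, by = person_id]
  cnt <- ev$N[match(pred$person_id, ev$person_id)]
  cnt[is.na(cnt)] <- 0
  bins2 <- as.integer(cut(cnt, quantile(cnt, 0:5 / 5), include.lowest = TRUE))
  tab2 <- adjusted_record_counts(reg, pred, bins2, iv$feature_cutoff)
  allb2 <- tab2[tab2$category == "all", ]
  expect_gt(allb2$mean_adjusted[5], allb2$mean_adjusted[1])
})
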