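test_that("preprocessor is fitted on training data only", {
  world <- cached_world()
  stats <- world$stats
  co <- world$cohort
  reg <- world$reg
  cutoff <- world$spec$splits$train$feature_cutoff

  # vocabulary = codes seen pre-cutoff among training persons
  tr_ids <- co[split == "train", person_id]
  want <- sort(unique(reg$events[person_id %in% tr_ids &
                                   event_date <= cutoff, code]))
  expect_equal(names(stats$code_index), want)
  expect_equal(unname(stats$code_index), seq_along(want) + 1L)  # dense, PAD=0/UNK=1

  # prevalence by direct count
  some <- sample(want, 5)
  for (cd in some) {
    cnt <- uniqueN(reg$events[person_id %in% tr_ids & code == cd &
                                event_date <= cutoff, person_id])
    expect_equal(unname(stats$code_prevalence[cd]), cnt / length(tr_ids))
  }
  expect_error(fit_preprocessor(reg, character(), cutoff, cutoff + 93),
               "empty")
})

test_that("zero-variance continuous feature warns and gets SD 1", {
  reg <- tiny_registry(60L, seed = 61)
  reg$persons$birth_date <- as.Date("1950-06-15")  # constant age
  expect_warning(
    st <- fit_preprocessor(reg, reg$persons$person_id,
                           as.Date("2017-09-30"), as.Date("2018-01-01")),
    "zero-variance")
  expect_equal(st$continuous$age_at_index$sd, 1)
})

test_that("row cap, deduplication and cutoff containment", {
  world <- cached_world()
  reg <- world$reg
  stats <- world$stats
  cutoff <- world$spec$splits$train$feature_cutoff

  # a person with 150 distinct codes in one age year -> exactly 100 kept
  pid <- reg$persons$person_id[1]
  bd <- reg$persons$birth_date[1]
  ay <- 40L
  d0 <- bd + round(ay * 365.25) + 10
  stopifnot(d0 < cutoff)
  extra <- data.table(
    person_id = pid,
    code = sprintf("dx_%04d", 1:150),
    category = "secondary_diagnosis",
    event_date = d0 + (0:149) %% 300)
  reg2 <- reg
  reg2$events <- rbind(reg$events[person_id != pid], extra, extra)  # + dupes
  ep <- encode_longitudinal(reg2, pid, cutoff, stats,
                            world$spec$splits$train$interval_start, seed = 5)
  row <- ep$code_matrix[ay + 1, ]
  nz <- row[row != 0]
  expect_equal(length(nz), 100L)
  expect_false(any(duplicated(nz)))

  # duplicates collapse: a code recorded 5x appears once
  reg3 <- reg
  reg3$events <- rbind(
    reg$events[person_id != pid],
    data.table(person_id = pid, code = "rx_0001",
               category = "drug_purchase",
               event_date = rep(d0, 5)))
  ep3 <- encode_longitudinal(reg3, pid, cutoff, stats,
                             world$spec$splits$train$interval_start)
  expect_equal(sum(ep3$code_matrix == stats$code_index[["rx_0001"]]), 1L)

  # no events at all -> all-PAD matrix with T rows
  reg4 <- reg
  reg4$events <- reg$events[person_id != pid]
  ep4 <- encode_longitudinal(reg4, pid, cutoff, stats,
                             world$spec$splits$train$interval_start)
  expect_true(all(ep4$code_matrix == 0L))
  expect_equal(nrow(ep4$code_matrix),
               floor(age_years(bd, cutoff)) + 1)

  # cutoff before birth errors
  expect_error(encode_longitudinal(reg, pid, bd - 1, stats,
                                   as.Date("2018-01-01")), "birth")
})

test_that("temporal containment: no encoded code postdates the cutoff", {
  world <- cached_world()
  reg <- world$reg
  stats <- world$stats
  cutoff <- world$spec$splits$train$feature_cutoff
  co <- world$cohort[split == "train"][1:80]
  enc <- encode_cohort(reg, co, stats, cutoff,
                       world$spec$splits$train$interval_start, seed = 9)
  # audit against raw events: per person, encoded code set (excluding UNK)
  # equals the distinct pre-cutoff mapped code set
  for (i in seq_len(40)) {
    got <- setdiff(unique(unlist(as_shap_person(enc, i)$rows)), 1L)
    raw <- reg$events[person_id == co$person_id[i] & event_date <= cutoff,
                      unique(code)]
    want <- sort(unname(stats$code_index[raw[raw %in% names(stats$code_index)]]))
    expect_equal(sort(got), want)
  }
})

test_that("cohort encoding is deterministic and matches the per-person route", {
  world <- cached_world()
  co <- world$cohort[split == "valid"][1:40]
  e1 <- encode_split(world, "valid", seed = 7)
  e2 <- encode_split(world, "valid", seed = 7)
  expect_identical(e1[names(e1) != "fixed"], e2[names(e2) != "fixed"])
  expect_identical(e1$fixed, e2$fixed)

  iv <- world$spec$splits$valid
  for (i in c(1L, 17L)) {
    single <- encode_longitudinal(world$reg, co$person_id[i],
                                  iv$feature_cutoff, world$stats,
                                  iv$interval_start, seed = 7)
    j <- match(co$person_id[i], e1$person_id)
    whole <- encoded_person(e1, j)
    expect_identical(single$code_matrix, whole$code_matrix)
    expect_equal(single$age_vector, whole$age_vector)
  }
})

test_that("fixed encoding: standardization, imputation, unknown levels", {
  world <- cached_world()
  reg <- world$reg
  stats <- world$stats
  iv <- world$spec$splits$train
  tr_ids <- world$cohort[split == "train", person_id]
  X <- encode_fixed(reg, tr_ids, stats, iv$interval_start)

  # age is never missing: transformed training column has mean 0, SD 1
  expect_lt(abs(mean(X[, "age_at_index"])), 1e-9)
  expect_lt(abs(sd(X[, "age_at_index"]) - 1), 1e-9)

  # missing pension -> imputed to mean (z = 0) and flagged
  miss <- is.na(reg$persons[match(tr_ids, person_id), pension_level])
  expect_true(all(X[miss, "pension_level"] == 0))
  expect_equal(X[, "pension_level_missing"], as.numeric(miss))
  # complete records carry no missingness flags
  flags <- X[, grepl("_missing$", colnames(X)), drop = FALSE]
  expect_true(all(rowSums(flags[!miss, , drop = FALSE]) == 0))

  # one-hot columns include a MISSING level; unknown level warns
  expect_true("region=MISSING" %in% colnames(X))
  reg2 <- reg
  reg2$persons$region[match(tr_ids[1], reg2$persons$person_id)] <- "atlantis"
  expect_warning(X2 <- encode_fixed(reg2, tr_ids[1], stats,
                                    iv$interval_start), "unknown level")
  expect_equal(unname(X2[1, "region=MISSING"]), 1)
})

test_that("binarize: popcount equals distinct pre-cutoff code count", {
  world <- cached_world()
  iv <- world$spec$splits$train
  ids <- world$cohort[split == "train", person_id][1:60]
  X <- binarize(world$reg, ids, world$stats, iv$feature_cutoff,
                iv$interval_start)
  vocab <- names(world$stats$code_index)
  for (i in c(1, 30, 60)) {
    raw <- world$reg$events[person_id == ids[i] &
                              event_date <= iv$feature_cutoff, unique(code)]
    expect_equal(sum(X[i, vocab]), length(intersect(raw, vocab)))
  }
  expect_true(all(as.matrix(X[, vocab]) %in% c(0, 1)))
  expect_equal(colnames(X), c(vocab, "age_at_index", "male"))
  # no events -> all-zero code bits
  ghost <- world$cohort[split == "train", person_id]
  no_ev <- setdiff(ghost, unique(world$reg$events$person_id))
  if (length(no_ev)) {
    X0 <- binarize(world$reg, no_ev[1], world$stats, iv$feature_cutoff,
                   iv$interval_start)
    expect_equal(sum(X0[1, vocab]), 0)
  }
})
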