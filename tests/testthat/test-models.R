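test_that("recurrent_spec validates fields", {
  expect_error(recurrent_spec(dropout = 1), "dropout")
  expect_error(recurrent_spec(hidden_dim = 0), "positive")
  sp <- recurrent_spec()
  expect_equal(sp$embedding_dim, 250L)
  expect_equal(sp$hidden_dim, 250L)
  expect_equal(sp$dropout, 0.46)
  expect_equal(sp$learning_rate, 4e-4)
  expect_equal(sp$weight_decay, 7.4e-6)
  expect_equal(sp$batch_size, 200L)
})

test_that("recurrent model learns a separable planted signal", {
  # one code present iff future case -> near-perfect validation AUC
  set.seed(301)
  mk <- function(n, seed) {
    set.seed(seed)
    y <- rbinom(n, 1, 0.3)
    toy_encoded(n, y, function(i, yi) {
      lapply(1:4, function(r) {
        rc <- if (yi == 1 && r == 3) 2L else integer()
        if (runif(1) < 0.5) rc <- c(rc, 3L)
        rc
      })
    })
  }
  tr <- mk(3000, 1); va <- mk(800, 2)
  sp <- recurrent_spec(embedding_dim = 24, hidden_dim = 24, dropout = 0.1,
                       learning_rate = 5e-3, batch_size = 100,
                       max_epochs = 8, patience = 8)
  fit <- train_recurrent(tr, va, sp, seed = 4)
  expect_gte(auc(va$label, predict(fit, va)), 0.95)

  # training log shape
  expect_true(all(c("epoch", "loss", "valid_auc") %in% names(fit$log)))
})

test_that("predictions are deterministic and permutation-invariant", {
  set.seed(302)
  y <- rbinom(400, 1, 0.3)
  tr <- toy_encoded(400, y, function(i, yi) {
    list(sample(2:5, 3), integer(), sample(2:5, 2))
  })
  va <- toy_encoded(100, rbinom(100, 1, 0.3), function(i, yi) {
    list(sample(2:5, 2), c(2L), integer())
  })
  sp <- recurrent_spec(embedding_dim = 8, hidden_dim = 8, dropout = 0.2,
                       batch_size = 50, max_epochs = 2, patience = 5)
  fit <- train_recurrent(tr, va, sp, seed = 1)
  p1 <- predict(fit, va)
  p2 <- predict(fit, va)
  expect_identical(p1, p2)
  expect_equal(length(p1), 100L)
  expect_true(all(p1 >= 0 & p1 <= 1))

  # permuting the codes within an age-year row changes nothing (sum pooling)
  va2 <- va
  for (g in seq_len(length(va2$code_ptr) - 1)) {
    len <- va2$code_ptr[g + 1] - va2$code_ptr[g]
    if (len > 1) {
      k <- va2$code_ptr[g] + seq_len(len)
      va2$codes[k] <- rev(va2$codes[k])
    }
  }
  expect_equal(predict(fit, va2), p1, tolerance = 1e-6)

  # preprocessor hash guard
  va3 <- va
  va3$stats_hash <- "other"
  expect_error(predict(fit, va3), "hash")

  # single-class labels refuse to train
  tr0 <- tr; tr0$label <- rep(0L, 400)
  expect_error(train_recurrent(tr0, va, sp), "single-class")
})

test_that("seeded retraining reproduces metrics", {
  set.seed(303)
  y <- rbinom(500, 1, 0.25)
  tr <- toy_encoded(500, y, function(i, yi) {
    list(c(if (yi) 2L else integer(), sample(3:6, 2)), integer())
  })
  va <- toy_encoded(200, rbinom(200, 1, 0.25), function(i, yi) {
    list(c(if (yi) 2L else integer(), sample(3:6, 1)))
  })
  sp <- recurrent_spec(embedding_dim = 8, hidden_dim = 8, dropout = 0.3,
                       batch_size = 100, max_epochs = 3, patience = 5)
  f1 <- train_recurrent(tr, va, sp, seed = 11)
  f2 <- train_recurrent(tr, va, sp, seed = 11)
  a1 <- auc(va$label, predict(f1, va))
  a2 <- auc(va$label, predict(f2, va))
  expect_lt(abs(a1 - a2), 0.005)  # same machine, same seed: identical
})

test_that("baseline recovers generating coefficients and closed form", {
  set.seed(304)
  n <- 50000
  age <- runif(n, 20, 95)
  male <- rbinom(n, 1, 0.49)
  lp <- -5 + 0.08 * age  # no sex effect planted
  y <- rbinom(n, 1, plogis(lp))
  fit <- train_baseline(age, male, y)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coef["age"] - 0.08) / se["age"], 3)
  expect_lt(abs(fit$coef["(Intercept)"] - -5) / se["(Intercept)"], 3)

  # predict equals the closed-form logistic
  p <- predict(fit, age[1:5], male[1:5])
  expect_equal(unname(p),
               unname(plogis(fit$coef[1] + fit$coef[2] * age[1:5] +
                               fit$coef[3] * male[1:5])))
  # monotone in age for fixed sex when beta_age > 0
  expect_true(all(diff(predict(fit, 20:90, rep(1, 71))) > 0))

  # fitted-model AUC close to the true generating score's AUC
  expect_lt(abs(auc(y, predict(fit, age, male)) - auc(y, plogis(lp))),
            0.01)
  expect_error(train_baseline(age, male, rep(0, n)), "single-class")
})

test_that("baseline flags separation and falls back to ridge", {
  age <- c(rep(30, 50), rep(80, 50))
  y <- c(rep(0, 50), rep(1, 50))
  fit <- train_baseline(age, rep(0, 100), y)
  expect_true(fit$separation_fallback)
  expect_true(all(is.finite(fit$coef)))
})

test_that("comparator grids are exactly the printed ones", {
  gl <- comparator_grid("penalized_logistic")
  expect_equal(nrow(gl), 12L)
  expect_setequal(unique(gl$penalty), c("L1", "L2"))
  expect_setequal(unique(gl$C), c(0.001, 0.01, 0.1, 1, 10, 100))
  gt <- comparator_grid("gbdt")
  expect_equal(nrow(gt), 243L)
  expect_setequal(unique(gt$learning_rate), c(0.01, 0.05, 0.1))
  expect_setequal(unique(gt$max_depth), c(3L, 5L, 7L))
  expect_setequal(unique(gt$nrounds), c(50L, 100L, 150L))
  expect_error(train_comparator("gbdt", matrix(0, 4, 2), c(0, 1, 0, 1),
                                grid = data.frame()), "empty")
})

test_that("penalized logistic: C -> infinity approaches unpenalized fit", {
  set.seed(305)
  n <- 400
  x1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x1))
  X <- cbind(x1 = x1, x2 = rnorm(n))
  f_big <- mortclock:::fit_pl(X, y, "L2", 1e6)
  f_ref <- glm(y ~ X, family = binomial())
  expect_equal(as.numeric(f_big$beta), unname(coef(f_ref)[2:3]),
               tolerance = 0.02)
})

test_that("comparator CV selects the argmax and refits", {
  set.seed(306)
  n <- 300
  X <- matrix(rbinom(n * 12, 1, 0.3), n, 12,
              dimnames = list(NULL, paste0("c", 1:12)))
  y <- rbinom(n, 1, plogis(-1 + 2 * X[, 1] + 1.5 * X[, 2] - X[, 3]))
  grid <- expand.grid(penalty = c("L1", "L2"), C = c(0.01, 1),
                      stringsAsFactors = FALSE)
  fit <- train_comparator("penalized_logistic", X, y, grid = grid, seed = 3)
  expect_equal(max(fit$cv$mean_cv_auc),
               fit$cv$mean_cv_auc[which(paste(fit$cv$penalty, fit$cv$C) ==
                                          paste(fit$best$penalty,
                                                fit$best$C))])
  expect_true(all(fit$cv$mean_cv_auc <= max(fit$cv$mean_cv_auc)))
  p <- predict(fit, X)
  expect_gte(auc(y, p), 0.6)

  # gbdt on a small grid learns the same signal and is seed-reproducible
  grid2 <- expand.grid(learning_rate = 0.1, max_depth = 3L,
                       subsample = c(0.75, 1), colsample = 1, nrounds = 50L)
  f2 <- train_comparator("gbdt", X, y, grid = grid2, seed = 4)
  f3 <- train_comparator("gbdt", X, y, grid = grid2, seed = 4)
  expect_gte(auc(y, predict(f2, X)), 0.7)
  expect_identical(predict(f2, X), predict(f3, X))
})

test_that("prediction_set validates and carries attributes", {
  expect_error(prediction_set("a", 1, 1.2), "probabilities")
  ps <- prediction_set(c("a", "b"), c(1, 0), c(0.9, 0.2),
                       event_week = c(10L, NA),
                       attributes = data.frame(age = c(80, 30),
                                               sex = c("male", "female")))
  expect_s3_class(ps, "prediction_set")
  expect_equal(surv_time(ps), c(10L, 52L))
  expect_true(ps$censored[2] && !ps$censored[1])
})
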