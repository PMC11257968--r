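#' Hyperparameter grids for the comparator models
#'
#' The printed contract: penalized logistic regression varies penalty
#' {L1, L2} x C {0.001, 0.01, 0.1, 1, 10, 100} (12 points); boosted trees
#' vary learning rate {0.01, 0.05, 0.1} x max depth {3, 5, 7} x row
#' subsample {0.5, 0.75, 1} x feature subsample {0.5, 0.75, 1} x boosting
#' rounds {50, 100, 150} (243 points).
#'
#' @param kind "penalized_logistic" or "gbdt".
#' @return data.frame, one row per grid point.
#' @export
comparator_grid <- function(kind = c("penalized_logistic", "gbdt")) {
  kind <- match.arg(kind)
  if (kind == "penalized_logistic") {
    expand.grid(penalty = c("L1", "L2"),
                C = c(0.001, 0.01, 0.1, 1, 10, 100),
                stringsAsFactors = FALSE)
  } else {
    expand.grid(learning_rate = c(0.01, 0.05, 0.1),
                max_depth = c(3L, 5L, 7L),
                subsample = c(0.5, 0.75, 1.0),
                colsample = c(0.5, 0.75, 1.0),
                nrounds = c(50L, 100L, 150L))
  }
}

#' @keywords internal
fit_pl <- function(X, y, penalty, C) {
  # scikit-learn's C is an inverse penalty on the summed loss; glmnet
  # penalizes the mean loss, so lambda = 1 / (C * n)
  glmnet::glmnet(X, y, family = "binomial",
                 alpha = if (penalty == "L1") 1 else 0,
                 lambda = 1 / (C * length(y)), standardize = FALSE)
}

#' @keywords internal
predict_pl <- function(fit, X) {
  as.numeric(predict(fit, X, type = "response"))
}

#' Train a comparator model by grid search + 3-fold CV
#'
#' Binary presence features (see [binarize()]) feed either a penalized
#' logistic regression (glmnet) or gradient-boosted trees (built-in
#' implementation). The full printed grid is scored by mean 3-fold
#' cross-validated AUC; the best point is refit on the whole training
#' split.
#'
#' @param kind "penalized_logistic" or "gbdt".
#' @param X feature matrix (sparse `dgCMatrix` or dense).
#' @param y binary labels.
#' @param grid grid data.frame (default [comparator_grid()]).
#' @param cv_folds number of CV folds (default 3).
#' @param seed integer seed (fold assignment, tree subsampling).
#' @return object of class `mortclock_comparator` with the fitted model,
#'   the chosen grid point and the full CV table.
#' @export
train_comparator <- function(kind = c("penalized_logistic", "gbdt"), X, y,
                             grid = comparator_grid(kind), cv_folds = 3L,
                             seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid) || nrow(grid) == 0L) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  if (length(unique(y)) < 2L) stop("single-class labels", call. = FALSE)
  n <- length(y)
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  Xd <- if (kind == "gbdt") as.matrix(X) else X
  cv_auc <- matrix(NA_real_, nrow(grid), cv_folds)
  for (gi in seq_len(nrow(grid))) {
    for (k in seq_len(cv_folds)) {
      tr <- folds != k
      sc <- if (kind == "penalized_logistic") {
        fit <- fit_pl(Xd[tr, , drop = FALSE], y[tr],
                      grid$penalty[gi], grid$C[gi])
        predict_pl(fit, Xd[!tr, , drop = FALSE])
      } else {
        pars <- c(as.list(grid[gi, ]), lambda = 1.0,
                  seed = derive_seed(seed, paste0("cv", gi, "_", k)))
        fit <- gbdt_train_cpp(Xd[tr, , drop = FALSE], y[tr], pars)
        as.numeric(gbdt_predict_cpp(fit, Xd[!tr, , drop = FALSE]))
      }
      yk <- y[!tr]
      cv_auc[gi, k] <- if (length(unique(yk)) < 2L) NA_real_ else
        auc(yk, sc)
    }
  }
  mean_auc <- rowMeans(cv_auc, na.rm = TRUE)
  best <- which.max(mean_auc)
  model <- if (kind == "penalized_logistic") {
    fit_pl(Xd, y, grid$penalty[best], grid$C[best])
  } else {
    pars <- c(as.list(grid[best, ]), lambda = 1.0,
              seed = derive_seed(seed, "refit"))
    gbdt_train_cpp(Xd, y, pars)
  }
  structure(list(kind = kind, model = model, best = grid[best, ],
                 cv = cbind(grid, mean_cv_auc = mean_auc),
                 feature_names = colnames(X)),
            class = "mortclock_comparator")
}

#' @export
print.mortclock_comparator <- function(x, ...) {
  cat(sprintf("<mortclock_comparator> %s; best grid point:\n", x$kind))
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' @param object a `mortclock_comparator`.
#' @param X feature matrix matching training columns.
#' @param ... unused.
#' @rdname train_comparator
#' @export
predict.mortclock_comparator <- function(object, X, ...) {
  if (!is.null(object$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names)) {
    stop("feature columns do not match the trained comparator",
         call. = FALSE)
  }
  if (object$kind == "penalized_logistic") {
    predict_pl(object$model, X)
  } else {
    as.numeric(gbdt_predict_cpp(object$model, as.matrix(X)))
  }
}

#' Assemble a prediction set
#'
#' The common currency of the evaluation, fairness and explainability
#' modules: per person the binary label, the model score, the event week
#' (cases) / censoring week 52 (controls), and the attribute columns used
#' for subgroup slicing.
#'
#' @param person_id character ids.
#' @param y binary labels.
#' @param score probabilities in `[0, 1]`.
#' @param event_week integer weeks (NA for controls).
#' @param censored logical.
#' @param attributes optional data.frame of per-person attributes (age,
#'   sex, sensitive attributes...).
#' @return data.table of class `prediction_set`.
#' @export
prediction_set <- function(person_id, y, score, event_week = NULL,
                           censored = NULL, attributes = NULL) {
  n <- length(person_id)
  stopifnot(length(y) == n, length(score) == n)
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop("scores must be probabilities in [0, 1]", call. = FALSE)
  }
  out <- data.table(person_id = person_id, y = as.integer(y),
                    score = as.numeric(score))
  out[, event_week := if (is.null(event_week)) NA_integer_ else
    as.integer(event_week)]
  out[, censored := if (is.null(censored)) y == 0L else censored]
  if (!is.null(attributes)) out <- cbind(out, as.data.table(attributes))
  setattr(out, "class", c("prediction_set", class(out)))
  out
}

#' Survival time on the 52-week grid (event week or censoring at 52)
#' @param pred a `prediction_set`.
#' @return integer weeks.
#' @export
surv_time <- function(pred) {
  ifelse(pred$y == 1L, pred$event_week, 52L)
}
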