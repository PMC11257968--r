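#' Recurrent model hyperparameters
#'
#' Defaults are the tuned optimum used throughout: embedding and hidden
#' dimensions 250, dropout 0.46 after the recurrent layer, learning rate
#' 4e-4, L2 weight decay 7.4e-6, batch size 200. Early stopping monitors
#' validation AUC with the given patience and restores the best epoch's
#' weights.
#'
#' @param embedding_dim,hidden_dim layer sizes (positive integers).
#' @param dropout dropout rate on the final hidden state, in `[0, 1)`.
#' @param learning_rate,weight_decay Adam step size and L2 penalty.
#' @param batch_size minibatch size.
#' @param max_epochs,patience early-stopping schedule.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return object of class `recurrent_spec`.
#' @export
recurrent_spec <- function(embedding_dim = 250L, hidden_dim = 250L,
                           dropout = 0.46, learning_rate = 4e-4,
                           weight_decay = 7.4e-6, batch_size = 200L,
                           max_epochs = 50L, patience = 5L, seed = 1L) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)",
                                        call. = FALSE)
  if (embedding_dim < 1 || hidden_dim < 1) {
    stop("embedding_dim and hidden_dim must be positive", call. = FALSE)
  }
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim), dropout = dropout,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "recurrent_spec")
}

#' @keywords internal
ragged_payload <- function(enc) {
  list(codes = enc$codes, code_ptr = enc$code_ptr, row_ptr = enc$row_ptr,
       age_std = enc$age_std, fixed = unname(enc$fixed),
       label = enc$label)
}

#' Train the gated recurrent risk model
#'
#' Per age-year step the embeddings of the step's distinct codes are summed
#' and concatenated with that step's standardized age; a GRU layer runs over
#' the steps; dropout is applied to the final hidden state, the fixed
#' feature vector is concatenated, and an affine map with logistic output
#' yields the one-year death probability. Binary cross-entropy is minimized
#' by Adam at the spec's learning rate and L2 penalty, with early stopping
#' on validation AUC.
#'
#' @param train,valid `encoded_cohort`s (same preprocessor).
#' @param spec a [recurrent_spec()].
#' @param seed overrides `spec$seed` when given.
#' @param verbose print per-epoch loss and validation AUC.
#' @return object of class `mortclock_rnn` (weights, training log,
#'   preprocessor hash).
#' @export
train_recurrent <- function(train, valid, spec = recurrent_spec(),
                            seed = spec$seed, verbose = FALSE) {
  stopifnot(inherits(train, "encoded_cohort"),
            inherits(valid, "encoded_cohort"))
  if (train$stats_hash != valid$stats_hash) {
    stop("train and valid encodings come from different preprocessors",
         call. = FALSE)
  }
  if (length(unique(train$label)) < 2L) {
    stop("training labels are single-class", call. = FALSE)
  }
  if (length(unique(valid$label)) < 2L) {
    stop("validation labels are single-class", call. = FALSE)
  }
  params <- c(unclass(spec), list(seed = as.integer(seed),
                                  vocab_size = train$vocab_size,
                                  verbose = isTRUE(verbose)))
  fit <- gru_train_cpp(ragged_payload(train), ragged_payload(valid), params)
  structure(list(weights = fit$weights, log = fit$log,
                 best_epoch = fit$best_epoch,
                 best_valid_auc = fit$best_valid_auc,
                 spec = spec, stats_hash = train$stats_hash,
                 fixed_cols = colnames(train$fixed)),
            class = "mortclock_rnn")
}

#' @export
print.mortclock_rnn <- function(x, ...) {
  cat(sprintf("<mortclock_rnn> best epoch %d, valid AUC %.4f\n",
              x$best_epoch, x$best_valid_auc))
  invisible(x)
}

#' Predict death probabilities from an encoded cohort
#'
#' Deterministic (dropout disabled). Refuses encodings produced by a
#' different preprocessor than the one the model was trained with.
#'
#' @param object a `mortclock_rnn`.
#' @param enc an `encoded_cohort`.
#' @param ... unused.
#' @return numeric probability vector.
#' @export
predict.mortclock_rnn <- function(object, enc, ...) {
  stopifnot(inherits(enc, "encoded_cohort"))
  if (!is.null(object$stats_hash) && enc$stats_hash != object$stats_hash) {
    stop("encoding preprocessor hash does not match the model's",
         call. = FALSE)
  }
  as.numeric(gru_predict_cpp(object$weights, ragged_payload(enc)))
}
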