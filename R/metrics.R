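#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a uniformly chosen case outscores a uniformly chosen
#' control, with score ties counted 1/2; computed from average ranks.
#'
#' @param y binary labels (both classes required).
#' @param score numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y, score) {
  y <- as.numeric(y)
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) {
    stop("AUC needs both classes (subgroups require >= 5 in the minority ",
         "class; see the subgroup guard)", call. = FALSE)
  }
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step interpolation over descending score thresholds with tied scores
#' grouped: AUPRC = sum over threshold steps of (recall increment) x
#' (precision at that threshold).
#'
#' @param y binary labels (at least one case).
#' @param score numeric scores.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(y, score) {
  y <- as.numeric(y)
  npos <- sum(y == 1)
  if (npos == 0) stop("AUPRC needs at least one case", call. = FALSE)
  o <- order(score, decreasing = TRUE)
  ys <- y[o]
  ss <- score[o]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  # keep only the last index of each tied-score block
  last <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Mean squared error between scores and labels (Brier score)
#'
#' @param y binary labels.
#' @param score probabilities.
#' @return mean of `(score - y)^2`.
#' @export
brier <- function(y, score) mean((score - as.numeric(y))^2)

#' Percentile-bootstrap confidence interval for the AUC
#'
#' Resamples (y, score) pairs with replacement `B` times; single-class
#' resamples are redrawn (their count is reported). The interval is the
#' 2.5th and 97.5th percentile of the bootstrap AUC distribution.
#'
#' @param y binary labels.
#' @param score scores.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return named vector `c(lo, hi)`; attribute `redraws` counts redrawn
#'   single-class resamples.
#' @export
bootstrap_auc_ci <- function(y, score, B = 1000L, seed = 1L, conf = 0.95) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  n <- length(y)
  redraws <- 0L
  aucs <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
        redraws <<- redraws + 1L
      }
      auc(y[idx], score[idx])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(aucs, c(alpha, 1 - alpha), names = FALSE)
  structure(c(lo = ci[1], hi = ci[2]), redraws = redraws)
}

#' Permutation test for an AUC difference between two groups
#'
#' Statistic: `AUC_A - AUC_B`. Group membership of the pooled (y, score)
#' records is permuted preserving group sizes; the one-sided p-value is
#' `(1 + #{permuted diff >= observed}) / (B + 1)` (add-one smoothing); the
#' two-sided variant compares absolute differences. Groups must have at
#' least 5 in their minority class, otherwise a skip status is returned
#' instead of a silent result.
#'
#' @param yA,scoreA labels and scores of group A.
#' @param yB,scoreB labels and scores of group B.
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @param two_sided compare `|diff|` instead of `diff`.
#' @return list with `observed` (AUC_A - AUC_B), `p`, `status`
#'   ("ok" or "skipped: ..." with p = NA).
#' @export
permutation_auc_diff_test <- function(yA, scoreA, yB, scoreB, B = 1000L,
                                      seed = 1L, two_sided = FALSE) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  guard <- function(y) min(sum(y == 1), sum(y == 0)) >= 5
  if (!guard(yA) || !guard(yB)) {
    return(list(observed = NA_real_, p = NA_real_,
                status = "skipped: fewer than 5 in a minority class"))
  }
  obs <- auc(yA, scoreA) - auc(yB, scoreB)
  y <- c(yA, yB)
  s <- c(scoreA, scoreB)
  nA <- length(yA)
  n <- length(y)
  perm <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, nA)
      inA <- logical(n)
      inA[idx] <- TRUE
      if (min(sum(y[inA] == 1), sum(y[inA] == 0)) == 0 ||
          min(sum(y[!inA] == 1), sum(y[!inA] == 0)) == 0) {
        return(NA_real_)
      }
      auc(y[inA], s[inA]) - auc(y[!inA], s[!inA])
    }, numeric(1))
  })
  perm <- perm[!is.na(perm)]
  stat <- if (two_sided) abs(perm) else perm
  ref <- if (two_sided) abs(obs) else obs
  list(observed = obs, p = (1 + sum(stat >= ref)) / (length(stat) + 1),
       status = "ok")
}

#' Calibration table
#'
#' Bins scores and compares mean predicted probability with the observed
#' death rate per bin. `equal_samples` (default) uses score-quantile bins
#' with equal sample counts; `equal_cases` places bin edges so each bin
#' holds an equal number of cases.
#'
#' @param y binary labels.
#' @param score probabilities.
#' @param n_bins number of bins (default 10).
#' @param strategy "equal_samples" or "equal_cases".
#' @return data.table: bin, n, n_cases, mean_predicted, observed_rate.
#' @export
calibration_curve <- function(y, score, n_bins = 10L,
                              strategy = c("equal_samples", "equal_cases")) {
  strategy <- match.arg(strategy)
  y <- as.numeric(y)
  if (strategy == "equal_cases" && sum(y == 1) < n_bins) {
    stop("fewer cases than bins under equal_cases binning", call. = FALSE)
  }
  bin <- if (strategy == "equal_samples") {
    r <- rank(score, ties.method = "first")
    as.integer(ceiling(r / length(score) * n_bins))
  } else {
    case_scores <- sort(score[y == 1])
    sizes <- largest_remainder(length(case_scores), rep(1 / n_bins, n_bins))
    edges <- case_scores[cumsum(sizes)][-n_bins]
    findInterval(score, edges, left.open = TRUE) + 1L
  }
  dt <- data.table(bin = bin, y = y, score = score)
  out <- dt[, .(n = .N, n_cases = sum(y), mean_predicted = mean(score),
                observed_rate = mean(y)), keyby = bin]
  out[]
}
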