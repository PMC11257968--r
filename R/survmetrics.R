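#' Harrell's concordance index
#'
#' Over comparable pairs — the earlier time is an uncensored event and the
#' other subject's time is later, or equal with the other subject censored —
#' the fraction in which the higher score goes with the earlier event, score
#' ties counting 1/2.
#'
#' @param event_week integer event/censoring weeks (1..52).
#' @param censored logical (TRUE = censored at `event_week`).
#' @param score risk scores (higher = earlier death expected).
#' @return C-index in `[0, 1]`.
#' @export
c_index <- function(event_week, censored, score) {
  t <- as.numeric(event_week)
  d <- !censored
  n <- length(t)
  conc <- 0
  comp <- 0
  # chunked O(n^2) comparison; fine for cohort-scale n
  chunk <- max(1L, floor(2e7 / n))
  for (s0 in seq(1L, n, by = chunk)) {
    ii <- s0:min(n, s0 + chunk - 1L)
    dt_lt <- outer(t[ii], t, "<")
    dt_eq <- outer(t[ii], t, "==")
    cmp <- (dt_lt | (dt_eq & outer(rep(TRUE, length(ii)), censored, "&"))) &
      d[ii]
    if (!any(cmp)) next
    sgn <- outer(score[ii], score, ">") + 0.5 * outer(score[ii], score, "==")
    comp <- comp + sum(cmp)
    conc <- conc + sum(sgn[cmp])
  }
  if (comp == 0) stop("no comparable pairs", call. = FALSE)
  conc / comp
}

#' Cumulative/dynamic time-dependent AUC
#'
#' At horizon `t`, cases are subjects with an uncensored event at or before
#' `t`; controls are subjects event-free beyond `t` — an event or censoring
#' after `t`, or censoring at exactly `t` (on the weekly grid, censoring at
#' week `t` means the subject was observed event-free through week `t`;
#' in particular administrative censoring at week 52 makes t = 52 coincide
#' with the binary AUC). Subjects censored strictly before `t` are
#' excluded.
#'
#' @param event_week event/censoring weeks.
#' @param censored logical.
#' @param score risk scores.
#' @param t horizon week.
#' @return list with `auc` (NA when undefined), `status`, `n_cases`,
#'   `n_controls`.
#' @export
time_dependent_auc <- function(event_week, censored, score, t) {
  tt <- as.numeric(event_week)
  case <- !censored & tt <= t
  control <- tt > t | (censored & tt == t)
  if (!any(case) || !any(control)) {
    return(list(auc = NA_real_, status = "skipped: no cases (or no controls) by t",
                n_cases = sum(case), n_controls = sum(control)))
  }
  keep <- case | control
  list(auc = auc(as.numeric(case[keep]), score[keep]), status = "ok",
       n_cases = sum(case), n_controls = sum(control))
}

#' Weekly time-dependent AUC curve
#'
#' @param event_week,censored,score as in [time_dependent_auc()].
#' @param weeks horizons (default 1..52).
#' @return data.table: week, auc (NA where undefined), status.
#' @export
td_auc_curve <- function(event_week, censored, score, weeks = 1:52) {
  rbindlist(lapply(weeks, function(w) {
    r <- time_dependent_auc(event_week, censored, score, w)
    data.table(week = w, auc = r$auc, status = r$status)
  }))
}

#' Kaplan-Meier estimator with exponential-Greenwood band
#'
#' Product-limit survival estimate on the weekly grid with the 95%
#' log(-log) ("exponential Greenwood") confidence band, which stays inside
#' `[0, 1]` by construction.
#'
#' @param event_week event/censoring weeks.
#' @param censored logical.
#' @param conf confidence level (default 0.95).
#' @return data.table: week (0..52), at_risk, events, surv, lo, hi.
#' @export
kaplan_meier <- function(event_week, censored, conf = 0.95) {
  stopifnot(length(event_week) >= 1)
  tt <- as.integer(event_week)
  d <- !censored
  z <- qnorm(1 - (1 - conf) / 2)
  weeks <- 0:52
  surv <- numeric(length(weeks))
  lo <- hi <- numeric(length(weeks))
  at_risk <- events <- integer(length(weeks))
  s <- 1
  vsum <- 0  # Greenwood sum d / (n (n - d))
  for (i in seq_along(weeks)) {
    w <- weeks[i]
    if (w == 0) {
      at_risk[i] <- length(tt)
      surv[i] <- 1; lo[i] <- 1; hi[i] <- 1
      next
    }
    n_w <- sum(tt >= w)
    d_w <- sum(tt == w & d)
    at_risk[i] <- n_w
    events[i] <- d_w
    if (n_w > 0 && d_w > 0) {
      s <- s * (1 - d_w / n_w)
      if (n_w > d_w) vsum <- vsum + d_w / (n_w * (n_w - d_w))
    }
    surv[i] <- s
    if (s <= 0 || s >= 1) {
      lo[i] <- s; hi[i] <- s
    } else {
      se <- sqrt(vsum) / abs(log(s))
      cll <- log(-log(s))
      lo[i] <- exp(-exp(cll + z * se))
      hi[i] <- exp(-exp(cll - z * se))
    }
  }
  data.table(week = weeks, at_risk = at_risk, events = events,
             surv = surv, lo = lo, hi = hi)
}

#' Percentile risk groups and death fractions
#'
#' Assigns percentile ranks of the score (average ranks for ties) and cuts
#' them into low (1-90), medium (91-95) and high (96-100) risk groups; also
#' returns the death fraction per fine percentile bin above the lower cut.
#'
#' @param score risk scores.
#' @param y binary labels (for the death-fraction tables).
#' @param cuts percentile cuts, default `c(90, 95)`.
#' @return list: `group` (factor low/medium/high per person), `summary`
#'   (per-group n, deaths, death fraction, deaths share), `fine`
#'   (per-percentile-bin death fraction above `cuts[1]`).
#' @export
risk_groups <- function(score, y, cuts = c(90, 95)) {
  n <- length(score)
  pct <- rank(score, ties.method = "average") / n * 100
  if (length(unique(score)) == 1L) {
    warning("all scores identical: every person lands in the low-risk group",
            call. = FALSE)
  }
  group <- cut(pct, breaks = c(-Inf, cuts, Inf),
               labels = c("low", "medium", "high"))
  dt <- data.table(group = group, y = as.numeric(y), pct = pct)
  summary <- dt[, .(n = .N, deaths = sum(y), death_fraction = mean(y)),
                keyby = group]
  summary[, deaths_share := deaths / sum(deaths)]
  fine <- dt[pct > cuts[1],
             .(n = .N, death_fraction = mean(y)),
             keyby = .(percentile = ceiling(pct))]
  list(group = group, summary = summary[], fine = fine[])
}

#' Full evaluation report
#'
#' Binary, calibration and survival metrics for one prediction set.
#'
#' @param pred a `prediction_set`.
#' @param B bootstrap resamples for the AUC CI.
#' @param n_bins calibration bins.
#' @param seed integer seed.
#' @return list of class `eval_report`.
#' @export
evaluate_predictions <- function(pred, B = 1000L, n_bins = 10L, seed = 1L) {
  tt <- surv_time(pred)
  ci <- bootstrap_auc_ci(pred$y, pred$score, B = B, seed = seed)
  rep <- list(
    n = nrow(pred), n_cases = sum(pred$y == 1),
    auc = auc(pred$y, pred$score),
    auc_ci = ci,
    auprc = auprc(pred$y, pred$score),
    brier = brier(pred$y, pred$score),
    calibration = calibration_curve(pred$y, pred$score, n_bins),
    c_index = c_index(tt, pred$censored & pred$y == 0L, pred$score),
    td_auc = td_auc_curve(tt, pred$censored & pred$y == 0L, pred$score),
    risk_groups = risk_groups(pred$score, pred$y)[c("summary", "fine")],
    km = kaplan_meier(tt, pred$censored & pred$y == 0L)
  )
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d (%d cases)\n  AUC %.4f (%.4f-%.4f)  AUPRC %.4f  Brier %.5f  C-index %.4f\n",
    x$n, x$n_cases, x$auc, x$auc_ci[1], x$auc_ci[2], x$auprc, x$brier,
    x$c_index))
  invisible(x)
}
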