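#' Subgroup AUC: group identification
#'
#' Identifiability of a subgroup's deaths within the whole population: AUC
#' over the subgroup's cases pooled with ALL controls. Returns a skip
#' status (not an error) when the subgroup has fewer than 5 cases.
#'
#' @param pred a `prediction_set`.
#' @param subgroup_mask logical vector over `pred` rows.
#' @param B bootstrap resamples for the CI (0 = skip CI).
#' @param seed integer seed.
#' @return one-row data.table (`subgroup_report`).
#' @export
group_identification_auc <- function(pred, subgroup_mask, B = 0L,
                                     seed = 1L) {
  keep <- (pred$y == 1 & subgroup_mask) | pred$y == 0
  n_cases <- sum(pred$y == 1 & subgroup_mask)
  n_controls <- sum(pred$y == 0)
  if (n_cases < 5L) {
    return(subgroup_row("identification", n_cases, n_controls, NA_real_,
                        NA_real_, NA_real_,
                        "skipped: fewer than 5 cases in subgroup"))
  }
  a <- auc(pred$y[keep], pred$score[keep])
  ci <- c(NA_real_, NA_real_)
  if (B > 0) ci <- bootstrap_auc_ci(pred$y[keep], pred$score[keep], B, seed)
  subgroup_row("identification", n_cases, n_controls, a, ci[1], ci[2], "ok")
}

#' Subgroup AUC: group differentiation
#'
#' Discrimination within the subgroup only (both cases and controls drawn
#' from the subgroup) — performance after subgroup membership is
#' conditioned away. Skips when either class has fewer than 5 members in
#' the subgroup.
#'
#' @inheritParams group_identification_auc
#' @return one-row data.table (`subgroup_report`).
#' @export
group_differentiation_auc <- function(pred, subgroup_mask, B = 0L,
                                      seed = 1L) {
  n_cases <- sum(pred$y == 1 & subgroup_mask)
  n_controls <- sum(pred$y == 0 & subgroup_mask)
  if (min(n_cases, n_controls) < 5L) {
    return(subgroup_row("differentiation", n_cases, n_controls, NA_real_,
                        NA_real_, NA_real_,
                        "skipped: fewer than 5 in a minority class"))
  }
  a <- auc(pred$y[subgroup_mask], pred$score[subgroup_mask])
  ci <- c(NA_real_, NA_real_)
  if (B > 0) ci <- bootstrap_auc_ci(pred$y[subgroup_mask],
                                    pred$score[subgroup_mask], B, seed)
  subgroup_row("differentiation", n_cases, n_controls, a, ci[1], ci[2], "ok")
}

#' @keywords internal
subgroup_row <- function(mode, n_cases, n_controls, auc, lo, hi, status) {
  data.table(mode = mode, n_cases = n_cases, n_controls = n_controls,
             auc = auc, ci_lo = lo, ci_hi = hi, status = status)
}

#' Equal-case binning of a continuous attribute
#'
#' Bin edges sit at case-count quantiles of the attribute so every bin
#' holds an equal number of cases (+/- 1); controls fall into bins by the
#' same edges.
#'
#' @param attribute numeric attribute values.
#' @param y binary labels.
#' @param n_bins number of bins.
#' @return integer bin assignment (1..n_bins) for every subject.
#' @export
equal_case_bins <- function(attribute, y, n_bins) {
  cases <- attribute[y == 1]
  if (length(cases) < n_bins) {
    stop("fewer cases than bins", call. = FALSE)
  }
  if (length(unique(cases)) < n_bins) {
    stop("degenerate bin edges: attribute (nearly) constant among cases",
         call. = FALSE)
  }
  cs <- sort(cases)
  sizes <- largest_remainder(length(cs), rep(1 / n_bins, n_bins))
  edges <- cs[cumsum(sizes)][-n_bins]
  findInterval(attribute, edges, left.open = TRUE) + 1L
}

#' Threshold maximizing the geometric mean of sensitivity and specificity
#'
#' Scans every distinct score as a cutpoint (score >= threshold classifies
#' positive) and returns the classification metrics at the maximizer of
#' sqrt(TPR x TNR); ties take the lowest threshold.
#'
#' @param y binary labels.
#' @param score scores.
#' @return list: threshold, tpr, fpr, tnr, accuracy, gmean.
#' @export
gmean_threshold <- function(y, score) {
  y <- as.numeric(y)
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) stop("both classes required", call. = FALSE)
  if (length(unique(score)) == 1L) {
    warning("constant scores: threshold is degenerate", call. = FALSE)
  }
  thr <- sort(unique(score))
  o <- order(score)
  ys <- y[o]; ss <- score[o]
  # at threshold t: positives are scores >= t
  below <- findInterval(thr, ss, left.open = TRUE)  # count of scores < t
  cum_pos <- cumsum(ys)
  pos_below <- c(0, cum_pos)[below + 1]             # cases with score < t
  tpr <- (npos - pos_below) / npos
  fpr <- (nneg - (below - pos_below)) / nneg
  gm <- sqrt(tpr * (1 - fpr))
  best <- which.max(gm)  # which.max takes the first (lowest threshold) tie
  metrics_at_threshold(y, score, thr[best])
}

#' Classification metrics at a fixed probability threshold
#'
#' @param y binary labels.
#' @param score scores.
#' @param threshold classify `score >= threshold` as positive.
#' @return list: threshold, tpr, fpr, tnr, accuracy, gmean.
#' @export
metrics_at_threshold <- function(y, score, threshold) {
  y <- as.numeric(y)
  pos <- score >= threshold
  tp <- sum(pos & y == 1); fn <- sum(!pos & y == 1)
  fp <- sum(pos & y == 0); tn <- sum(!pos & y == 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  list(threshold = threshold, tpr = tpr, fpr = fpr, tnr = 1 - fpr,
       accuracy = (tp + tn) / length(y),
       gmean = sqrt(tpr * (1 - fpr)))
}

#' Exact age-sex matching between two arms
#'
#' Within every (age-year, sex) stratum the larger arm is randomly
#' downsampled to the smaller arm's count; strata present in only one arm
#' are dropped. Requires `age` and `sex` columns on the prediction set.
#'
#' @param pred a `prediction_set` with `age` and `sex` columns.
#' @param group_mask logical: arm membership.
#' @param age_resolution stratum width in years (default 1).
#' @param seed integer seed.
#' @return the matched subset of `pred` (both arms), with the mask in
#'   column `.group`.
#' @export
match_age_sex <- function(pred, group_mask, age_resolution = 1, seed = 1L) {
  stopifnot(all(c("age", "sex") %in% names(pred)))
  stratum <- paste(floor(pred$age / age_resolution), pred$sex)
  inA <- which(group_mask)
  inB <- which(!group_mask)
  common <- intersect(unique(stratum[inA]), unique(stratum[inB]))
  if (!length(common)) stop("no overlapping (age, sex) strata",
                            call. = FALSE)
  keep <- with_seed(seed, {
    unlist(lapply(common, function(s) {
      a <- inA[stratum[inA] == s]
      b <- inB[stratum[inB] == s]
      m <- min(length(a), length(b))
      c(if (length(a) > m) sample(a, m) else a,
        if (length(b) > m) sample(b, m) else b)
    }))
  })
  keep <- sort(keep)
  out <- pred[keep]
  out[, .group := group_mask[keep]]
  out
}

#' Intersectional disadvantage report
#'
#' The four-attribute fairness audit: per attribute (unmarried, immigrant,
#' mental-health diagnosis, low pension — pension dichotomized at the
#' case-equalizing cut, i.e. the median pension among cases), the
#' differentiation AUC of the disadvantaged vs advantaged group with a
#' permutation p-value (one-sided: advantaged minus disadvantaged); the
#' AUC by number of simultaneous disadvantages (0..4); and all 2^4
#' intersection sizes.
#'
#' @param pred a `prediction_set` carrying logical columns `unmarried`,
#'   `immigrant`, `mental_health_dx` and numeric `pension` (the report is
#'   restricted to rows with a defined pension, i.e. the 65+ population).
#' @param B permutations for the p-values.
#' @param seed integer seed.
#' @return list: `attributes` (per-attribute table), `by_count`,
#'   `intersections`.
#' @export
disadvantage_report <- function(pred, B = 1000L, seed = 1L) {
  need <- c("unmarried", "immigrant", "mental_health_dx", "pension")
  stopifnot(all(need %in% names(pred)))
  dt <- pred[!is.na(pred$pension)]
  # case-equalizing pension dichotomy: equal cases in both pension groups
  cut_p <- stats::median(dt$pension[dt$y == 1])
  dt[, low_pension := pension < cut_p]
  flags <- c("unmarried", "immigrant", "mental_health_dx", "low_pension")
  attr_rows <- rbindlist(lapply(flags, function(f) {
    m <- dt[[f]]
    dis <- group_differentiation_auc(dt, m)
    adv <- group_differentiation_auc(dt, !m)
    pt <- permutation_auc_diff_test(dt$y[!m], dt$score[!m],
                                    dt$y[m], dt$score[m],
                                    B = B, seed = derive_seed(seed, f))
    data.table(attribute = f,
               n_disadvantaged = sum(m), n_advantaged = sum(!m),
               auc_disadvantaged = dis$auc, auc_advantaged = adv$auc,
               p = pt$p,
               status = if (dis$status == "ok" && adv$status == "ok")
                 pt$status else "skipped: subgroup guard")
  }))
  count <- rowSums(as.matrix(dt[, ..flags]))
  by_count <- rbindlist(lapply(sort(unique(count)), function(k) {
    r <- group_differentiation_auc(dt, count == k)
    data.table(n_disadvantages = k, n = sum(count == k), auc = r$auc,
               status = r$status)
  }))
  key <- apply(as.matrix(dt[, ..flags]), 1, function(z)
    paste(as.integer(z), collapse = ""))
  all_keys <- apply(expand.grid(rep(list(0:1), 4)), 1, paste, collapse = "")
  inter <- data.table(combo = all_keys)
  setnames(inter, "combo", "combo")
  inter[, n := vapply(combo, function(k) sum(key == k), numeric(1))]
  list(attributes = attr_rows, by_count = by_count,
       intersections = inter[], pension_cut = cut_p, flags = flags)
}

#' Age/sex-adjusted record counts per bin
#'
#' Regresses each person's total pre-cutoff record count on age and a sex
#' indicator, z-normalizes the residuals, and reports the mean per bin —
#' overall and per event category. A flat profile means record volume
#' differences across bins are explained by demography alone.
#'
#' @param registry a registry.
#' @param pred a `prediction_set` with `age` and `sex` columns.
#' @param bins integer bin assignment per `pred` row (e.g. from
#'   [equal_case_bins()]).
#' @param cutoff count only events dated at or before this date.
#' @return data.table: bin x category (plus "all") mean adjusted count.
#' @export
adjusted_record_counts <- function(registry, pred, bins, cutoff) {
  stopifnot(all(c("age", "sex") %in% names(pred)))
  ev <- registry$events[person_id %in% pred$person_id &
                          event_date <= cutoff]
  adj <- function(count) {
    if (length(unique(pred$age)) < 2L) {
      stop("degenerate adjustment regression (constant age)", call. = FALSE)
    }
    fit <- lm(count ~ age + male,
              data = data.frame(count = count, age = pred$age,
                                male = as.numeric(pred$sex == "male")))
    r <- residuals(fit)
    s <- sd(r)
    if (!is.finite(s) || s == 0) s <- 1
    (r - mean(r)) / s
  }
  cats <- c("all", sort(unique(ev$category)))
  rbindlist(lapply(cats, function(cc) {
    sub <- if (cc == "all") ev else ev[category == cc]
    cnt <- sub[, .N, by = person_id]
    count <- cnt$N[match(pred$person_id, cnt$person_id)]
    count[is.na(count)] <- 0
    z <- adj(count)
    data.table(category = cc, bin = sort(unique(bins)),
               mean_adjusted = vapply(sort(unique(bins)),
                                      function(b) mean(z[bins == b]),
                                      numeric(1)))
  }))
}
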