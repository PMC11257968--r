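#' Fit the preprocessor on the training split
#'
#' Computes everything the encoders need, strictly from training-split
#' persons and their pre-cutoff history: the code vocabulary (index 0 is
#' reserved for PAD, 1 for UNK; real codes get dense indices from 2), each
#' code's training prevalence (fraction of training persons with at least
#' one pre-cutoff occurrence), code-to-category mapping, means/SDs/modes and
#' categorical level lists (with an explicit MISSING level) for the
#' fixed-over-time features, and the mean/SD of age-at-step used to
#' standardize the age sequence.
#'
#' @param registry a registry.
#' @param train_ids person_ids of the training split.
#' @param cutoff last usable feature date for the training split.
#' @param interval_start training predictive-interval start (used for the
#'   age-at-index fixed feature).
#' @return object of class `preprocessor_stats`.
#' @export
fit_preprocessor <- function(registry, train_ids, cutoff, interval_start) {
  if (length(train_ids) == 0L) stop("training cohort is empty", call. = FALSE)
  persons <- registry$persons[match(train_ids, person_id)]
  ev <- registry$events[person_id %in% train_ids & event_date <= cutoff]
  vocab <- sort(unique(ev$code))
  code_index <- setNames(seq_along(vocab) + 1L, vocab)  # 0 PAD, 1 UNK
  prev <- ev[, .(n = uniqueN(person_id)), by = code]
  code_prevalence <- setNames(rep(0, length(vocab)), vocab)
  code_prevalence[prev$code] <- prev$n / length(train_ids)
  code_category <- setNames(
    ev$category[match(vocab, ev$code)], vocab)

  sd1 <- function(x, what) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance continuous feature '", what,
              "': SD set to 1", call. = FALSE)
      s <- 1
    }
    s
  }
  age_idx <- age_years(persons$birth_date, interval_start)
  pen <- persons$pension_level
  pen_obs <- pen[!is.na(pen)]
  cont <- list(
    age_at_index = list(mean = mean(age_idx),
                        sd = sd1(age_idx, "age_at_index")),
    pension_level = list(
      mean = if (length(pen_obs)) mean(pen_obs) else 0,
      sd = if (length(pen_obs)) sd1(pen_obs, "pension_level") else 1,
      all_missing = length(pen_obs) == 0L)
  )
  mode_of <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(0)
    as.numeric(names(sort(table(x), decreasing = TRUE))[1])
  }
  ordinal <- list(
    immigrant = list(mode = mode_of(as.numeric(persons$immigrant))),
    mental_health_dx = list(mode = mode_of(as.numeric(persons$mental_health_dx)))
  )
  categorical <- list(
    sex = c(sort(unique(persons$sex)), "MISSING"),
    region = c(sort(unique(persons$region)), "MISSING"),
    marital = c(sort(unique(persons$marital)), "MISSING")
  )
  # pooled moments of the age sequence (a + 0.5 for a = 0..T-1), computed in
  # closed form from the per-person number of age years T
  t_steps <- floor(pmax(age_years(persons$birth_date, cutoff), 0)) + 1
  n_steps <- sum(t_steps)
  s1 <- sum(t_steps^2 / 2)
  s2 <- sum((4 * t_steps^3 - t_steps) / 12)
  mu <- s1 / n_steps
  sdev <- sqrt(max(s2 / n_steps - mu^2, 1e-12))
  stats <- list(
    code_index = code_index,
    code_prevalence = code_prevalence,
    code_category = code_category,
    continuous = cont,
    ordinal = ordinal,
    categorical = categorical,
    age_step = list(mean = mu, sd = sdev),
    n_train = length(train_ids)
  )
  stats$hash <- rlang::hash(stats[c("code_index", "continuous", "ordinal",
                                    "categorical", "age_step")])
  class(stats) <- "preprocessor_stats"
  stats
}

#' @keywords internal
row_cap <- 100L

#' Encode the fixed-over-time feature vector(s)
#'
#' Continuous features are standardized by training mean/SD with missing
#' values imputed at the mean and flagged; ordinal features are mode-imputed
#' and flagged; categorical features are one-hot encoded with an explicit
#' MISSING level (unknown levels at inference map to MISSING with a
#' warning).
#'
#' @param registry a registry.
#' @param ids person_ids to encode (row order of the result).
#' @param stats a `preprocessor_stats`.
#' @param interval_start the split's predictive-interval start (for the
#'   age-at-index feature).
#' @return numeric matrix, one row per person, with named columns.
#' @export
encode_fixed <- function(registry, ids, stats, interval_start) {
  persons <- registry$persons[match(ids, person_id)]
  n <- nrow(persons)
  cols <- list()
  age <- age_years(persons$birth_date, interval_start)
  cols$age_at_index <- (age - stats$continuous$age_at_index$mean) /
    stats$continuous$age_at_index$sd
  pen <- persons$pension_level
  pm <- is.na(pen)
  cs <- stats$continuous$pension_level
  pen_z <- (ifelse(pm, cs$mean, pen) - cs$mean) / cs$sd
  if (isTRUE(cs$all_missing)) pen_z[] <- 0
  cols$pension_level <- pen_z
  cols$pension_level_missing <- as.numeric(pm | isTRUE(cs$all_missing))
  for (nm in names(stats$ordinal)) {
    v <- as.numeric(persons[[nm]])
    miss <- is.na(v)
    v[miss] <- stats$ordinal[[nm]]$mode
    cols[[nm]] <- v
    cols[[paste0(nm, "_missing")]] <- as.numeric(miss)
  }
  for (nm in names(stats$categorical)) {
    lev <- stats$categorical[[nm]]
    v <- as.character(persons[[nm]])
    v[is.na(v)] <- "MISSING"
    unknown <- !(v %in% lev)
    if (any(unknown)) {
      warning(sum(unknown), " unknown level(s) of '", nm,
              "' mapped to MISSING", call. = FALSE)
      v[unknown] <- "MISSING"
    }
    oh <- matrix(0, n, length(lev),
                 dimnames = list(NULL, paste0(nm, "=", lev)))
    oh[cbind(seq_len(n), match(v, lev))] <- 1
    for (j in colnames(oh)) cols[[j]] <- oh[, j]
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}

#' Encode a cohort's longitudinal records (ragged form)
#'
#' The workhorse behind [encode_longitudinal()]: for every person, one row
#' per age year from birth (age year 0) to the age year at the feature
#' cutoff; each row holds the distinct vocabulary indices of codes recorded
#' in that age year on or before the cutoff (unseen codes map to UNK, then
#' duplicates collapse). Rows with more than 100 distinct entries are
#' reduced to a seeded uniform subsample of exactly 100, drawn once at
#' encoding time; the subsample seed is derived per (person, age year) so
#' single-person and whole-cohort encoding agree entry for entry.
#'
#' @param registry a registry.
#' @param cohort cohort data.table (rows define persons and order; needs
#'   person_id, label, event_week).
#' @param stats a `preprocessor_stats`.
#' @param cutoff last usable feature date.
#' @param interval_start predictive-interval start.
#' @param seed integer seed for row-cap subsampling.
#' @return object of class `encoded_cohort`: ragged code arrays
#'   (`codes`, `code_ptr`, `row_ptr`), standardized `age_std` per row,
#'   `fixed` matrix, labels and metadata.
#' @export
encode_cohort <- function(registry, cohort, stats, cutoff, interval_start,
                          seed = 1L) {
  ids <- cohort$person_id
  persons <- registry$persons[match(ids, person_id)]
  if (any(persons$birth_date > cutoff)) {
    stop("feature cutoff precedes a cohort member's birth date",
         call. = FALSE)
  }
  t_rows <- floor(age_years(persons$birth_date, cutoff)) + 1L
  ev <- registry$events[person_id %in% ids & event_date <= cutoff]
  if (nrow(ev)) {
    pix <- match(ev$person_id, ids)
    ay <- floor(age_years(persons$birth_date[pix], ev$event_date))
    idx <- stats$code_index[ev$code]
    idx[is.na(idx)] <- 1L  # UNK
    cell <- data.table(pix = pix, ay = as.integer(ay), idx = as.integer(idx))
    cell <- unique(cell)
    # enforce the 100-entry row cap with a per-row derived seed
    cnt <- cell[, .N, by = .(pix, ay)]
    over <- cnt[N > row_cap]
    if (nrow(over)) {
      setkey(cell, pix, ay)
      kept <- lapply(seq_len(nrow(over)), function(i) {
        rr <- cell[.(over$pix[i], over$ay[i])]
        s <- derive_seed(seed, paste0(ids[over$pix[i]], ":", over$ay[i]))
        rr[with_seed(s, sample.int(nrow(rr), row_cap))]
      })
      cell <- rbind(cell[!cnt[N > row_cap], on = c("pix", "ay")],
                    rbindlist(kept))
    }
    setorder(cell, pix, ay, idx)
  } else {
    cell <- data.table(pix = integer(), ay = integer(), idx = integer())
  }
  n <- length(ids)
  row_ptr <- c(0L, cumsum(t_rows))
  total_rows <- row_ptr[n + 1L]
  # per global row: counts of codes
  grow <- row_ptr[cell$pix] + cell$ay + 1L  # global row index (1-based)
  cnt_row <- integer(total_rows)
  if (length(grow)) {
    tb <- tabulate(grow, nbins = total_rows)
    cnt_row <- tb
  }
  code_ptr <- c(0L, cumsum(cnt_row))
  codes <- integer(length(grow))
  if (length(grow)) {
    o <- order(grow, cell$idx)
    codes <- cell$idx[o]
  }
  # standardized age per row
  ay_all <- sequence(t_rows) - 0.5
  age_std <- (ay_all - stats$age_step$mean) / stats$age_step$sd
  structure(list(
    person_id = ids,
    label = as.integer(cohort$label),
    event_week = cohort$event_week,
    t_rows = t_rows,
    row_ptr = row_ptr,
    code_ptr = code_ptr,
    codes = codes,
    age_std = age_std,
    fixed = encode_fixed(registry, ids, stats, interval_start),
    vocab_size = length(stats$code_index),
    stats_hash = stats$hash,
    cutoff = cutoff,
    interval_start = interval_start,
    seed = as.integer(seed)
  ), class = "encoded_cohort")
}

#' @export
print.encoded_cohort <- function(x, ...) {
  cat(sprintf(
    "<encoded_cohort> %d persons, %d age-year rows, %d code entries, %d fixed features\n",
    length(x$person_id), length(x$code_ptr) - 1L, length(x$codes),
    ncol(x$fixed)))
  invisible(x)
}

#' Extract one person's encoding as a dense matrix
#'
#' @param enc an `encoded_cohort`.
#' @param i person position.
#' @return list: `code_matrix` (T x 100 integer, PAD = 0, left-justified),
#'   `age_vector`, `fixed_vector`, `label`, `event_week`.
#' @export
encoded_person <- function(enc, i) {
  rows <- (enc$row_ptr[i] + 1L):enc$row_ptr[i + 1L]
  t_i <- length(rows)
  m <- matrix(0L, t_i, row_cap)
  for (r in seq_along(rows)) {
    g <- rows[r]
    cc <- enc$codes[seq_len(enc$code_ptr[g + 1L] - enc$code_ptr[g]) +
                      enc$code_ptr[g]]
    if (length(cc)) m[r, seq_along(cc)] <- cc
  }
  list(code_matrix = m,
       age_vector = enc$age_std[rows],
       fixed_vector = enc$fixed[i, ],
       label = enc$label[i],
       event_week = enc$event_week[i])
}

#' Encode a single person (dense contract form)
#'
#' Single-person convenience route over the cohort encoder; produces the
#' dense T x 100 code matrix, the standardized age vector and the fixed
#' vector.
#'
#' @param registry a registry.
#' @param pid person_id.
#' @param cutoff feature cutoff date.
#' @param stats a `preprocessor_stats`.
#' @param interval_start predictive-interval start.
#' @param seed row-cap subsampling seed.
#' @return see [encoded_person()].
#' @export
encode_longitudinal <- function(registry, pid, cutoff, stats,
                                interval_start = cutoff + 93, seed = 1L) {
  co <- data.table(person_id = pid, label = 0L, event_week = NA_integer_)
  enc <- encode_cohort(registry, co, stats, cutoff, interval_start, seed)
  encoded_person(enc, 1L)
}

#' Binary presence vectors for comparator models
#'
#' One column per vocabulary code: 1 iff the person has at least one
#' pre-cutoff occurrence of the code. Standardized age at the interval start
#' and a male indicator are appended, matching the comparator-model feature
#' contract.
#'
#' @param registry a registry.
#' @param ids person_ids (row order).
#' @param stats a `preprocessor_stats`.
#' @param cutoff feature cutoff date.
#' @param interval_start predictive-interval start.
#' @return a sparse `dgCMatrix` with named columns.
#' @export
binarize <- function(registry, ids, stats, cutoff, interval_start) {
  vocab <- names(stats$code_index)
  ev <- registry$events[person_id %in% ids & event_date <= cutoff &
                          code %in% vocab]
  pr <- unique(data.table(pix = match(ev$person_id, ids),
                          cix = match(ev$code, vocab)))
  persons <- registry$persons[match(ids, person_id)]
  age_z <- (age_years(persons$birth_date, interval_start) -
              stats$continuous$age_at_index$mean) /
    stats$continuous$age_at_index$sd
  male <- as.numeric(persons$sex == "male")
  X <- Matrix::sparseMatrix(
    i = c(pr$pix, seq_along(ids), seq_along(ids)),
    j = c(pr$cix, rep(length(vocab) + 1L, length(ids)),
          rep(length(vocab) + 2L, length(ids))),
    x = c(rep(1, nrow(pr)), age_z, male),
    dims = c(length(ids), length(vocab) + 2L),
    dimnames = list(NULL, c(vocab, "age_at_index", "male"))
  )
  X
}

#' Code-recency feature vectors
#'
#' Time-aware sibling of [binarize()]: one column per vocabulary code
#' holding `exp(-dt / tau)` where `dt` is the time in years since the
#' person's most recent pre-cutoff occurrence of the code (0 if the code
#' never occurred). Standardized age at the interval start is appended.
#' Useful for linear models that should see *when* something last
#' happened, not merely whether it ever did — presence bits are almost
#' invariant to record thinning, recency features are not, which matters
#' when auditing observation-bias effects.
#'
#' @param registry a registry.
#' @param ids person_ids (row order).
#' @param stats a `preprocessor_stats`.
#' @param cutoff feature cutoff date.
#' @param interval_start predictive-interval start.
#' @param tau recency-decay time constant in years.
#' @return a sparse `dgCMatrix` with named columns.
#' @export
recency_features <- function(registry, ids, stats, cutoff, interval_start,
                             tau = 1.5) {
  vocab <- names(stats$code_index)
  ev <- registry$events[person_id %in% ids & event_date <= cutoff &
                          code %in% vocab,
                        .(last = max(event_date)), by = .(person_id, code)]
  persons <- registry$persons[match(ids, person_id)]
  age_z <- (age_years(persons$birth_date, interval_start) -
              stats$continuous$age_at_index$mean) /
    stats$continuous$age_at_index$sd
  Matrix::sparseMatrix(
    i = c(match(ev$person_id, ids), seq_along(ids)),
    j = c(match(ev$code, vocab), rep(length(vocab) + 1L, length(ids))),
    x = c(exp(-as.numeric(cutoff - ev$last) / 365.25 / tau), age_z),
    dims = c(length(ids), length(vocab) + 1L),
    dimnames = list(NULL, c(vocab, "age_at_index")))
}
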