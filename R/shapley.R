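#' Extract one person as a mutable sequence object
#'
#' The explainability module manipulates persons as a list of per-age-year
#' code vectors plus the age sequence and fixed vector; this converts a row
#' of an `encoded_cohort`.
#'
#' @param enc an `encoded_cohort`.
#' @param i person position.
#' @return list: `rows` (list of integer code vectors), `age`, `fixed`.
#' @export
as_shap_person <- function(enc, i) {
  rows_idx <- (enc$row_ptr[i] + 1L):enc$row_ptr[i + 1L]
  rows <- lapply(rows_idx, function(g) {
    k <- enc$code_ptr[g + 1L] - enc$code_ptr[g]
    if (k == 0L) integer() else enc$codes[enc$code_ptr[g] + seq_len(k)]
  })
  list(rows = rows, age = enc$age_std[rows_idx], fixed = enc$fixed[i, ])
}

#' @keywords internal
persons_payload <- function(persons) {
  t_rows <- vapply(persons, function(p) length(p$rows), integer(1))
  row_ptr <- c(0L, cumsum(t_rows))
  all_rows <- unlist(lapply(persons, function(p) p$rows),
                     recursive = FALSE, use.names = FALSE)
  cnt <- vapply(all_rows, length, integer(1))
  list(
    codes = as.integer(unlist(all_rows, use.names = FALSE)),
    code_ptr = c(0L, cumsum(cnt)),
    row_ptr = as.integer(row_ptr),
    age_std = unlist(lapply(persons, `[[`, "age"), use.names = FALSE),
    fixed = do.call(rbind, lapply(persons, function(p) unname(p$fixed))),
    label = NULL
  )
}

#' @keywords internal
predict_persons <- function(model, persons) {
  if (is.function(model)) {
    vapply(persons, model, numeric(1))
  } else if (inherits(model, "mortclock_rnn")) {
    as.numeric(gru_predict_cpp(model$weights, persons_payload(persons)))
  } else {
    stop("model must be a mortclock_rnn or a function(person) -> prob",
         call. = FALSE)
  }
}

#' @keywords internal
mask_person <- function(person, keep_codes) {
  person$rows <- lapply(person$rows, function(r) r[r %in% keep_codes])
  person
}

#' @keywords internal
shap_metadata <- function(person, players, enc = NULL, stats = NULL) {
  meta <- data.table(code_index = players)
  if (!is.null(stats)) {
    vocab <- names(stats$code_index)
    nm <- ifelse(players == 1L, "UNK", vocab[players - 1L])
    meta[, code := nm]
    meta[, category := ifelse(players == 1L, "UNK",
                              unname(stats$code_category[nm]))]
    meta[, prevalence := ifelse(players == 1L, NA_real_,
                                unname(stats$code_prevalence[nm]))]
  }
  # age years (0-based) in which each player occurs
  occ <- lapply(players, function(cd) {
    which(vapply(person$rows, function(r) cd %in% r, logical(1))) - 1L
  })
  meta[, first_age_year := vapply(occ, min, integer(1))]
  meta[, last_age_year := vapply(occ, max, integer(1))]
  meta
}

#' Exact Shapley attributions for one person's longitudinal codes
#'
#' Players are the person's distinct codes; a coalition's value is the
#' model probability after deleting every non-member code from every
#' age-year row (rows re-compacted). The baseline f0 is the prediction with
#' no longitudinal codes at all. Phi is computed by full 2^n enumeration
#' (n <= 12), so additivity sum(phi) = f(full) - f0 holds to numerical
#' precision.
#'
#' @param model a `mortclock_rnn` or a `function(person) -> probability`.
#' @param person a person object from [as_shap_person()].
#' @param stats optional `preprocessor_stats` for code metadata.
#' @return list of class `attribution_set`: `phi` table, `f_full`, `f0`.
#' @export
exact_shapley <- function(model, person, stats = NULL) {
  players <- sort(unique(unlist(person$rows, use.names = FALSE)))
  n <- length(players)
  if (n > 12L) {
    stop("more than 12 distinct codes: use sampled_shapley()", call. = FALSE)
  }
  if (n == 0L) {
    f0 <- predict_persons(model, list(person))
    return(structure(list(phi = data.table(code_index = integer(),
                                           phi = numeric()),
                          f_full = f0, f0 = f0, mode = "exact"),
                     class = "attribution_set"))
  }
  masks <- 0:(2^n - 1)
  coal <- lapply(masks, function(m) {
    mask_person(person, players[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
  })
  v <- predict_persons(model, coal)
  lw <- lgamma(0:(n - 1) + 1) + lgamma(n - (0:(n - 1))) - lgamma(n + 1)
  size <- vapply(masks, function(m) sum(bitwAnd(m, 2^(seq_len(n) - 1)) > 0),
                 numeric(1))
  phi <- vapply(seq_len(n), function(i) {
    bit <- 2^(i - 1)
    without <- masks[bitwAnd(masks, bit) == 0]
    s <- size[without + 1]
    sum(exp(lw[s + 1]) * (v[without + bit + 1] - v[without + 1]))
  }, numeric(1))
  out <- shap_metadata(person, players, stats = stats)
  out[, phi := phi]
  structure(list(phi = out, f_full = v[2^n], f0 = v[1], mode = "exact"),
            class = "attribution_set")
}

#' Monte-Carlo (permutation) Shapley attributions
#'
#' Unbiased permutation estimator: for each of `n_permutations` random
#' orderings of the players, each player's marginal contribution when added
#' to the preceding players' coalition is recorded; phi-hat is the mean and
#' a per-player standard error is reported. Coalition values are cached, so
#' repeated prefixes cost one model call.
#'
#' @param model as in [exact_shapley()].
#' @param person a person object.
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed.
#' @param stats optional `preprocessor_stats` for metadata.
#' @return `attribution_set` with columns `phi` and `se`.
#' @export
sampled_shapley <- function(model, person, n_permutations = 50L, seed = 1L,
                            stats = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  players <- sort(unique(unlist(person$rows, use.names = FALSE)))
  n <- length(players)
  if (n == 0L) stop("person has no longitudinal codes", call. = FALSE)
  perms <- with_seed(seed, replicate(n_permutations, sample.int(n),
                                     simplify = FALSE))
  key <- function(set) paste0("k", paste(sort(set), collapse = ","))
  need <- new.env(parent = emptyenv())
  assign(key(integer()), TRUE, envir = need)
  for (pm in perms) {
    for (k in seq_len(n)) assign(key(pm[seq_len(k)]), TRUE, envir = need)
  }
  keys <- ls(need)
  sets <- lapply(keys, function(k) {
    k <- sub("^k", "", k)
    if (k == "") integer() else as.integer(strsplit(k, ",")[[1]])
  })
  vals <- predict_persons(model, lapply(sets, function(s) {
    mask_person(person, players[s])
  }))
  names(vals) <- keys
  contrib <- matrix(NA_real_, n_permutations, n)
  for (j in seq_along(perms)) {
    pm <- perms[[j]]
    prev <- vals[[key(integer())]]
    for (k in seq_len(n)) {
      cur <- vals[[key(pm[seq_len(k)])]]
      contrib[j, pm[k]] <- cur - prev
      prev <- cur
    }
  }
  out <- shap_metadata(person, players, stats = stats)
  out[, phi := colMeans(contrib)]
  out[, se := apply(contrib, 2, sd) / sqrt(n_permutations)]
  structure(list(phi = out, f_full = vals[[key(seq_len(n))]],
                 f0 = vals[[key(integer())]], mode = "sampled"),
            class = "attribution_set")
}

#' @export
print.attribution_set <- function(x, ...) {
  cat(sprintf("<attribution_set:%s> %d players, f(full)=%.4f f0=%.4f\n",
              x$mode, nrow(x$phi), x$f_full, x$f0))
  invisible(x)
}

#' Aggregate attributions across persons
#'
#' Mean absolute Shapley value per stratum: by feature `category`, by
#' `years_before_index` (calendar years between a player's most recent
#' occurrence and the predictive-interval start) or by training
#' `prevalence_bin`.
#'
#' @param attribution_sets list of `attribution_set`s (with metadata, i.e.
#'   computed with `stats`).
#' @param mode one of "category", "years_before_index", "prevalence_bin".
#' @param birth_years numeric vector (one per attribution set): birth year
#'   of each person — needed to convert age years to calendar years.
#' @param index_year predictive-interval start year.
#' @param prevalence_breaks bin edges for prevalence mode.
#' @return data.table: stratum, n_players, mean_abs_phi.
#' @export
aggregate_attributions <- function(attribution_sets,
                                   mode = c("category", "years_before_index",
                                            "prevalence_bin"),
                                   birth_years = NULL, index_year = NULL,
                                   prevalence_breaks = c(0, 0.001, 0.01,
                                                         0.05, 0.2, 1)) {
  mode <- match.arg(mode)
  tabs <- lapply(seq_along(attribution_sets), function(j) {
    ph <- copy(attribution_sets[[j]]$phi)
    if (nrow(ph) == 0L) return(NULL)
    if (mode == "years_before_index") {
      stopifnot(!is.null(birth_years), !is.null(index_year))
      ph[, stratum := pmax(index_year - (birth_years[j] + last_age_year), 0)]
    } else if (mode == "category") {
      ph[, stratum := category]
    } else {
      ph[, stratum := cut(prevalence, breaks = prevalence_breaks,
                          include.lowest = TRUE)]
    }
    ph
  })
  all <- rbindlist(tabs)
  if (nrow(all) == 0L) return(data.table(stratum = character(),
                                         n_players = integer(),
                                         mean_abs_phi = numeric()))
  out <- all[!is.na(stratum),
             .(n_players = .N, mean_abs_phi = mean(abs(phi))),
             keyby = stratum]
  out[]
}

#' Category permutation importance
#'
#' For every person, all codes NOT in the target category are replaced by
#' the non-category codes of a uniformly chosen other person (whole-history
#' swap aligned by age year); the AUC on the perturbed cohort is returned.
#' The higher the retained AUC, the more of the model's discrimination
#' lives inside the category. `category = "ALL"` permutes nothing.
#'
#' @param model a `mortclock_rnn` or function.
#' @param enc an `encoded_cohort` with labels.
#' @param category target category name or "ALL".
#' @param stats the `preprocessor_stats` (code-to-category map).
#' @param seed integer seed for donor choice.
#' @return list: `auc`, `category`.
#' @export
category_permutation_importance <- function(model, enc, category, stats,
                                            seed = 1L) {
  cats <- unique(stats$code_category)
  if (!(category %in% c(cats, "ALL"))) {
    stop("unknown category: ", category, call. = FALSE)
  }
  n <- length(enc$person_id)
  persons <- lapply(seq_len(n), function(i) as_shap_person(enc, i))
  if (category != "ALL") {
    idx_cat <- c("PAD", "UNK", unname(stats$code_category))
    in_cat <- which(idx_cat == category) - 1L  # code indices in category
    donors <- with_seed(seed, {
      d <- sample.int(n, n, replace = TRUE)
      shift <- d == seq_len(n)
      d[shift] <- (d[shift] %% n) + 1L  # never self-donate
      d
    })
    persons <- lapply(seq_len(n), function(i) {
      p <- persons[[i]]
      dn <- persons[[donors[i]]]
      t_i <- length(p$rows)
      t_d <- length(dn$rows)
      p$rows <- lapply(seq_len(t_i), function(r) {
        own <- p$rows[[r]][p$rows[[r]] %in% in_cat]
        don <- if (r <= t_d) {
          dn$rows[[r]][!(dn$rows[[r]] %in% in_cat)]
        } else integer()
        sort(unique(c(own, don)))
      })
      p
    })
  }
  sc <- predict_persons(model, persons)
  list(auc = auc(enc$label, sc), category = category)
}
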