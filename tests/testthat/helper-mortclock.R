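# Shared fixtures and independent oracles.
#
# Oracles deliberately use brute-force double loops / full enumeration and
# never call the package implementation they check.

suppressMessages(library(data.table))

# ---- brute-force metric oracles -------------------------------------------

auc_oracle <- function(y, score) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

cindex_oracle <- function(time, censored, score) {
  n <- length(time)
  conc <- 0; comp <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    comparable <- (!censored[i]) &&
      (time[i] < time[j] || (time[i] == time[j] && censored[j]))
    if (!comparable) next
    comp <- comp + 1
    conc <- conc + if (score[i] > score[j]) 1 else
      if (score[i] == score[j]) 0.5 else 0
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

td_auc_oracle <- function(time, censored, score, t) {
  case <- which(!censored & time <= t)
  ctrl <- which(time > t | (censored & time == t))
  s <- 0
  for (i in case) for (j in ctrl) {
    s <- s + if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
  }
  s / (length(case) * length(ctrl))
}

auprc_oracle <- function(y, score) {
  # step interpolation over descending unique thresholds
  thr <- sort(unique(score), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  npos <- sum(y == 1)
  for (t in thr) {
    sel <- score >= t
    prec <- sum(y[sel] == 1) / sum(sel)
    rec <- sum(y[sel] == 1) / npos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

gmean_oracle <- function(y, score) {
  best <- -1; best_thr <- NA
  for (t in sort(unique(score))) {
    pos <- score >= t
    tpr <- sum(pos & y == 1) / sum(y == 1)
    fpr <- sum(pos & y == 0) / sum(y == 0)
    g <- sqrt(tpr * (1 - fpr))
    if (g > best + 1e-15) { best <- g; best_thr <- t }
  }
  list(threshold = best_thr, gmean = best)
}

# exact Shapley by permutation-average definition (independent of the
# subset-weight formula used in the implementation)
shapley_perm_oracle <- function(value_fn, n) {
  perms <- combinat_perms(seq_len(n))
  phi <- numeric(n)
  for (pm in perms) {
    prev <- value_fn(integer())
    for (k in seq_len(n)) {
      cur <- value_fn(sort(pm[1:k]))
      phi[pm[k]] <- phi[pm[k]] + (cur - prev)
      prev <- cur
    }
  }
  phi / length(perms)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# ---- small-world fixtures --------------------------------------------------

# a tiny but fully exercised synthetic world, cached per test run
tiny_config <- function(n = 1500L, ...) {
  generator_config(n_persons = n, ...)
}

tiny_registry <- function(n = 1500L, seed = 123L, cfg = tiny_config(n)) {
  reg <- generate_population(cfg, seed = seed)
  reg <- simulate_events(reg, cfg, end_year = 2020L, seed = seed + 1L)
  simulate_mortality(reg, cfg, horizon = 2018:2020, seed = seed + 2L)
}

cached_world <- local({
  env <- new.env()
  function() {
    if (is.null(env$world)) {
      cfg <- tiny_config(4000L)
      reg <- tiny_registry(4000L, seed = 31L, cfg = cfg)
      spec <- split_spec()
      bc <- build_cohort(reg, spec, seed = 32L)
      stats <- fit_preprocessor(
        reg, bc$cohort[split == "train", person_id],
        spec$splits$train$feature_cutoff, spec$splits$train$interval_start)
      env$world <- list(cfg = cfg, reg = reg, spec = spec,
                        cohort = bc$cohort, tallies = bc$tallies,
                        stats = stats)
    }
    env$world
  }
})

encode_split <- function(world, s, seed = 77L) {
  encode_cohort(world$reg, world$cohort[split == s], world$stats,
                world$spec$splits[[s]]$feature_cutoff,
                world$spec$splits[[s]]$interval_start, seed = seed)
}

# a deterministic toy probability model over shap-person objects:
# logistic in counts of specific codes, ignores ages/fixed
toy_code_model <- function(weights, intercept = -1) {
  function(person) {
    codes <- unlist(person$rows, use.names = FALSE)
    lp <- intercept
    for (cd in names(weights)) {
      lp <- lp + weights[[cd]] * sum(codes == as.integer(cd))
    }
    plogis(lp)
  }
}

# hand-built encoded cohort for model tests (vocab size v, T rows each)
toy_encoded <- function(n, y, rows_fn, vocab = 5L, fixed = NULL,
                        age_fn = function(t_i) rep(0, t_i)) {
  codes <- integer(0); code_ptr <- 0L; row_ptr <- 0L; age <- numeric(0)
  for (i in seq_len(n)) {
    rws <- rows_fn(i, y[i])
    for (r in rws) {
      codes <- c(codes, r)
      code_ptr <- c(code_ptr, code_ptr[length(code_ptr)] + length(r))
    }
    row_ptr <- c(row_ptr, row_ptr[length(row_ptr)] + length(rws))
    age <- c(age, age_fn(length(rws)))
  }
  structure(list(
    person_id = as.character(seq_len(n)), label = as.integer(y),
    event_week = rep(NA_integer_, n),
    t_rows = diff(row_ptr), row_ptr = row_ptr, code_ptr = code_ptr,
    codes = codes, age_std = age,
    fixed = if (is.null(fixed)) matrix(0, n, 1) else fixed,
    vocab_size = as.integer(vocab), stats_hash = "toy", seed = 1L),
    class = "encoded_cohort")
}
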