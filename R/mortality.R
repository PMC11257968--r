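#' Hazard covariates at the start of a calendar year
#'
#' Builds, for every person alive (and not emigrated) on Jan 1 of `year`,
#' the design matrix of the generative death hazard: standardized age
#' `(age - 70)/10`, male indicator, latent frailty, and one recency term
#' `exp(-dt_k / tau)` per risk code (0 if the code never occurred before
#' Jan 1 of `year`). Exposed so that the planted-signal recovery check can
#' refit the generating model by maximum likelihood.
#'
#' @param registry registry with events simulated.
#' @param config a [generator_config()].
#' @param year calendar year.
#' @return data.table keyed by `person_id` with the covariate columns
#'   (`age10`, `male`, `frailty`, one `rc_<code>` per risk code).
#' @export
hazard_covariates <- function(registry, config = registry$config_echo,
                              year, risk_events = NULL) {
  persons <- registry$persons
  jan1 <- as.Date(sprintf("%d-01-01", year))
  dt <- data.table(
    person_id = persons$person_id,
    age10 = (age_years(persons$birth_date, jan1) - 70) / 10,
    male = as.numeric(persons$sex == "male"),
    frailty = persons$frailty
  )
  rc <- config$risk_codes
  if (nrow(rc)) {
    if (is.null(risk_events)) {
      risk_events <- registry$events[code %in% rc$code,
                                     .(person_id, code, event_date)]
    }
    ev <- risk_events[event_date < jan1,
                      .(last = max(event_date)), by = .(person_id, code)]
    for (i in seq_len(nrow(rc))) {
      cn <- paste0("rc_", rc$code[i])
      v <- numeric(nrow(dt))
      evi <- ev[code == rc$code[i]]
      if (nrow(evi)) {
        m <- match(evi$person_id, dt$person_id)
        keep <- !is.na(m)
        v[m[keep]] <-
          exp(-age_years(evi$last[keep], jan1) / config$hazard$tau)
      }
      set(dt, j = cn, value = v)
    }
  }
  dt
}

#' Annual death probabilities for one calendar year
#' @keywords internal
hazard_prob <- function(covars, hz, weights) {
  lp <- hz$beta0 + hz$beta_age * covars$age10 + hz$beta_sex * covars$male +
    hz$gamma * covars$frailty
  if (length(weights)) {
    rc_cols <- paste0("rc_", names(weights))
    for (i in seq_along(weights)) {
      lp <- lp + weights[i] * covars[[rc_cols[i]]]
    }
  }
  plogis(lp)
}

#' Simulate deaths over a horizon of years
#'
#' Year by year, every person alive and not emigrated at Jan 1 draws a
#' Bernoulli death with the configured discrete-time hazard (see
#' [generator_config()]). A death gets a day uniform within the year (week =
#' `ceiling(day-of-year / 7)` capped at 52), is always emitted to the
#' full-date register (source B) and always to the year-only register
#' (source A), whose year is correct with probability `register_agreement`
#' and otherwise perturbed by one year. A generic cause-of-death label is
#' drawn: with probability 0.7 a dying person whose strongest recent risk
#' code is k gets `cod_k`'s label; otherwise a uniform generic label.
#' Events after the death date are removed (registers stop at death).
#'
#' @param registry registry with events simulated through the horizon.
#' @param config a [generator_config()].
#' @param horizon integer vector of consecutive calendar years.
#' @param seed integer seed.
#' @return registry with `deaths` filled.
#' @export
simulate_mortality <- function(registry, config = registry$config_echo,
                               horizon = 2018:2020,
                               seed = config$seed + 2L) {
  validate_generator_config(config)
  ev_end <- attr(registry, "events_end_year")
  if (is.null(ev_end) || max(horizon) > ev_end) {
    stop("events must be simulated through the mortality horizon ",
         "(information leakage guard)", call. = FALSE)
  }
  persons <- registry$persons
  if (nrow(persons) == 0L) {
    registry$deaths <- empty_deaths()
    return(registry)
  }
  weights <- setNames(config$risk_codes$weight, config$risk_codes$code)
  rho <- config$register_agreement
  risk_events_all <- if (nrow(config$risk_codes)) {
    registry$events[code %in% config$risk_codes$code,
                    .(person_id, code, event_date)]
  } else NULL
  deaths <- with_seed(seed, {
    dead <- rep(FALSE, nrow(persons))
    out <- vector("list", length(horizon))
    for (j in seq_along(horizon)) {
      y <- horizon[j]
      jan1 <- as.Date(sprintf("%d-01-01", y))
      alive <- !dead & persons$birth_date < jan1 &
        (is.na(persons$emigrated_date) | persons$emigrated_date >= jan1)
      if (!any(alive)) next
      sub <- new_registry(persons[alive], empty_events(), config = config)
      cov <- hazard_covariates(sub, config, y,
                               risk_events = risk_events_all)
      h <- hazard_prob(cov, config$hazard, weights)
      dies <- runif(length(h)) < h
      if (!any(dies)) next
      widx <- which(alive)[dies]
      nd <- length(widx)
      day <- floor(runif(nd) * 365)
      ddate <- jan1 + day
      # generic cause-of-death label tilted by the strongest risk-code term
      cod <- sprintf("cod_%02d", sample.int(20L, nd, replace = TRUE))
      if (length(weights)) {
        contrib <- as.matrix(
          cov[dies, paste0("rc_", names(weights)), with = FALSE])
        contrib <- sweep(contrib, 2, weights, `*`)
        strongest <- max.col(contrib, ties.method = "first")
        fired <- contrib[cbind(seq_len(nd), strongest)] > 0.05
        take <- fired & runif(nd) < 0.7
        cod[take] <- sprintf("cod_%02d", strongest[take])
      }
      agree <- runif(nd) < rho
      year_a <- ifelse(agree, y, y + sample(c(-1L, 1L), nd, replace = TRUE))
      out[[j]] <- rbind(
        data.table(person_id = persons$person_id[widx], source = "B_full_date",
                   death_year = y, death_date = ddate, cod = cod),
        data.table(person_id = persons$person_id[widx], source = "A_year_only",
                   death_year = as.integer(year_a),
                   death_date = as.Date(NA), cod = cod)
      )
      dead[widx] <- TRUE
    }
    rbindlist(out)
  })
  if (is.null(deaths) || nrow(deaths) == 0L) {
    registry$deaths <- empty_deaths()
    return(registry)
  }
  setorder(deaths, person_id, source)
  registry$deaths <- deaths
  # registers stop at death: drop post-death events
  bdate <- deaths[source == "B_full_date", .(person_id, death_date)]
  ev <- merge(registry$events, bdate, by = "person_id", all.x = TRUE)
  ev <- ev[is.na(death_date) | event_date <= death_date]
  ev[, death_date := NULL]
  setorder(ev, person_id, event_date, category, code)
  registry$events <- ev
  registry
}
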