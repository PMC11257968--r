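#' Generate the synthetic person table
#'
#' Draws `n_persons` persons with birth dates uniform over the configured
#' birth-year range, sex at the configured female fraction, a categorical
#' region (10 regions with Zipf-decaying population shares), marital status,
#' immigration and mental-health-diagnosis flags, a latent standard-normal
#' frailty, an old-age pension level (log-normal, defined only for persons
#' aged 65+ on Jan 1 of `reference_year`) and, for a configured fraction,
#' an emigration date strictly before any predictive interval.
#'
#' Attributes are drawn independently of frailty and of each other, so in the
#' unbiased world (`disadvantage_dropout = 0`) none of the sensitive
#' attributes carries mortality signal — the fairness audit's null case.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; the draw is deterministic given (config, seed).
#' @return a `registry` (list with `persons`, empty `events` and `deaths`,
#'   and `config_echo`).
#' @export
generate_population <- function(config, seed = config$seed) {
  validate_generator_config(config)
  n <- config$n_persons
  persons <- with_seed(seed, {
    if (n == 0L) {
      empty_persons()
    } else {
      by1 <- config$birth_year_range[1]
      by2 <- config$birth_year_range[2]
      d1 <- as.Date(sprintf("%d-01-01", by1))
      d2 <- as.Date(sprintf("%d-12-31", by2))
      birth <- d1 + floor(runif(n) * (as.numeric(d2 - d1) + 1))
      sex <- ifelse(runif(n) < config$female_fraction, "female", "male")
      region <- paste0("region_", sprintf("%02d", sample.int(
        10L, n, replace = TRUE, prob = (1:10)^-0.8)))
      marital <- ifelse(runif(n) < 0.55, "married", "unmarried")
      immigrant <- runif(n) < 0.08
      mental <- runif(n) < 0.15
      frail <- rnorm(n)
      ref <- as.Date(sprintf("%d-01-01", config$reference_year))
      age_ref <- age_years(birth, ref)
      pension <- ifelse(age_ref >= 65,
                        round(exp(rnorm(n, log(1800), 0.5)), 2), NA_real_)
      emig <- rep(as.Date(NA), n)
      n_emig <- round(config$emigration_fraction * n)
      if (n_emig > 0) {
        idx <- sample.int(n, n_emig)
        w1 <- as.Date("2005-01-01")
        w2 <- as.Date("2016-12-31")
        emig[idx] <- w1 + floor(runif(n_emig) * (as.numeric(w2 - w1) + 1))
        # emigration cannot precede birth; late-born emigrants leave in youth
        emig[idx] <- pmax(emig[idx], birth[idx] + 365)
      }
      data.table(
        person_id = sprintf("p%07d", seq_len(n)),
        birth_date = birth, sex = sex, region = region,
        pension_level = pension, marital = marital,
        immigrant = immigrant, mental_health_dx = mental,
        frailty = frail, emigrated_date = emig
      )
    }
  })
  new_registry(persons = persons, config = config)
}

#' @keywords internal
empty_persons <- function() {
  data.table(
    person_id = character(), birth_date = as.Date(character()),
    sex = character(), region = character(), pension_level = numeric(),
    marital = character(), immigrant = logical(),
    mental_health_dx = logical(), frailty = numeric(),
    emigrated_date = as.Date(character())
  )
}

#' @keywords internal
empty_events <- function() {
  data.table(
    person_id = character(), code = character(), category = character(),
    event_date = as.Date(character())
  )
}

#' @keywords internal
empty_deaths <- function() {
  data.table(
    person_id = character(), source = character(), death_year = integer(),
    death_date = as.Date(character()), cod = character()
  )
}

#' Construct a registry container
#'
#' A registry bundles the three tables the pipeline consumes — persons,
#' longitudinal coded events, and death records from two sources — plus an
#' echo of the generating configuration.
#'
#' @param persons,events,deaths data.tables (see the CSV schemas in
#'   [write_registry()]).
#' @param config the generating [generator_config()] (echoed).
#' @return object of class `registry`.
#' @export
new_registry <- function(persons, events = empty_events(),
                         deaths = empty_deaths(), config = NULL) {
  reg <- list(persons = as.data.table(persons),
              events = as.data.table(events),
              deaths = as.data.table(deaths),
              config_echo = config)
  class(reg) <- "registry"
  reg
}

#' @export
print.registry <- function(x, ...) {
  cat(sprintf("<registry> %d persons, %d events, %d death records\n",
              nrow(x$persons), nrow(x$events), nrow(x$deaths)))
  invisible(x)
}

#' Validate registry referential integrity
#'
#' Every event and death must reference an existing person.
#' @param reg a registry.
#' @return the registry, invisibly; errors on orphan ids.
#' @export
validate_registry <- function(reg) {
  ids <- reg$persons$person_id
  bad_ev <- which(!(reg$events$person_id %in% ids))
  if (length(bad_ev)) {
    stop(sprintf("events row %d references unknown person_id '%s'",
                 bad_ev[1], reg$events$person_id[bad_ev[1]]), call. = FALSE)
  }
  bad_de <- which(!(reg$deaths$person_id %in% ids))
  if (length(bad_de)) {
    stop(sprintf("deaths row %d references unknown person_id '%s'",
                 bad_de[1], reg$deaths$person_id[bad_de[1]]), call. = FALSE)
  }
  invisible(reg)
}
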