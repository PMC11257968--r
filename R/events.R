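#' Simulate longitudinal coded events
#'
#' For every person, category and calendar year between the category's
#' register start year and `end_year`, the number of records is Poisson with
#' \eqn{\log \lambda = \log(base\_rate) + \alpha_c (age - 40)/10 +
#' \gamma_{evt} f} (the frailty loading applies to medical categories
#' only; socioeconomic rates are frailty-free). Codes are drawn Zipf over
#' the category vocabulary, so a minority of codes carries most records, as
#' in real coded registers. Event dates are uniform within the year, clipped
#' to be on/after birth and before any emigration date. No category emits a
#' record before its start year: the register simply did not exist.
#'
#' @param registry a registry with persons generated.
#' @param config a [generator_config()].
#' @param end_year last calendar year of event simulation (inclusive).
#' @param seed integer seed.
#' @return the registry with `events` filled and attribute
#'   `events_end_year` set (consumed by [simulate_mortality()]'s leakage
#'   guard).
#' @export
simulate_events <- function(registry, config = registry$config_echo,
                            end_year = 2020L, seed = config$seed + 1L) {
  validate_generator_config(config)
  persons <- registry$persons
  if (nrow(persons) == 0L) {
    registry$events <- empty_events()
    attr(registry, "events_end_year") <- as.integer(end_year)
    return(registry)
  }
  birth_year <- as.integer(format(persons$birth_date, "%Y"))
  emig_year <- ifelse(is.na(persons$emigrated_date), Inf,
                      as.integer(format(persons$emigrated_date, "%Y")))
  ev_list <- with_seed(seed, {
    lapply(names(config$category_specs), function(cat) {
      sp <- config$category_specs[[cat]]
      if (sp$base_rate <= 0) return(NULL)
      y_lo <- pmax(birth_year, sp$start_year)
      y_hi <- pmin(end_year, emig_year)
      n_y <- pmax(y_hi - y_lo + 1, 0)
      if (sum(n_y) == 0) return(NULL)
      pidx <- rep.int(seq_len(nrow(persons)), n_y)
      year <- unlist(lapply(which(n_y > 0),
                            function(i) y_lo[i]:y_hi[i]), use.names = FALSE)
      # date lookup tables: as.Date() on millions of strings is the hot path
      yr_rng <- min(year):max(year)
      jan1_tab <- as.Date(sprintf("%d-01-01", yr_rng))
      jul1_tab <- as.Date(sprintf("%d-07-01", yr_rng))
      mid <- jul1_tab[year - yr_rng[1] + 1L]
      age <- age_years(persons$birth_date[pidx], mid)
      loglam <- log(sp$base_rate) + sp$age_slope * (age - 40) / 10
      if (cat %in% medical_categories()) {
        loglam <- loglam + config$event_frailty * persons$frailty[pidx]
      }
      k <- rpois(length(loglam), pmin(exp(loglam), 30))
      keep <- k > 0
      if (!any(keep)) return(NULL)
      pidx <- rep.int(pidx[keep], k[keep])
      year <- rep.int(year[keep], k[keep])
      m <- length(pidx)
      V <- sp$vocabulary_size
      code_labels <- sprintf("%s_%04d", category_prefixes[[cat]],
                             seq_len(V))
      codes_i <- sample.int(V, m, replace = TRUE,
                            prob = (seq_len(V))^(-config$zipf_s))
      y0 <- jan1_tab[year - yr_rng[1] + 1L]
      dates <- y0 + floor(runif(m) * 365)  # uniform day-of-year
      dates <- pmax(dates, persons$birth_date[pidx])
      emig <- persons$emigrated_date[pidx]
      ok <- is.na(emig) | dates <= emig
      data.table(
        person_id = persons$person_id[pidx[ok]],
        code = code_labels[codes_i[ok]],
        category = cat,
        event_date = dates[ok]
      )
    })
  })
  events <- rbindlist(ev_list)
  if (nrow(events) == 0L) events <- empty_events()
  setorder(events, person_id, event_date, category, code)
  registry$events <- events
  attr(registry, "events_end_year") <- as.integer(end_year)
  registry
}
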