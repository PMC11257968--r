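#' Plant disadvantage-dependent record incompleteness
#'
#' Independently drops each *medical* event of every disadvantaged person
#' with probability `delta` (the `disadvantage_dropout` of the config unless
#' overridden). Socioeconomic events, deaths and fixed attributes are left
#' untouched: the planted mechanism is reduced healthcare observation, not
#' altered outcomes — the hypothesized route by which models become less
#' accurate for disadvantaged groups.
#'
#' @param registry registry with events simulated.
#' @param config a [generator_config()].
#' @param disadvantaged_mask logical vector, one entry per person (aligned
#'   with `registry$persons`); see [disadvantage_flags()].
#' @param delta dropout probability (default from config).
#' @param seed integer seed.
#' @return registry with thinned events.
#' @export
apply_observation_bias <- function(registry, config = registry$config_echo,
                                   disadvantaged_mask,
                                   delta = config$disadvantage_dropout,
                                   seed = config$seed + 3L) {
  if (length(disadvantaged_mask) != nrow(registry$persons)) {
    stop("disadvantaged_mask length (", length(disadvantaged_mask),
         ") does not match number of persons (", nrow(registry$persons), ")",
         call. = FALSE)
  }
  if (delta <= 0 || nrow(registry$events) == 0L) return(registry)
  dis_ids <- registry$persons$person_id[disadvantaged_mask]
  ev <- registry$events
  target <- ev$person_id %in% dis_ids & ev$category %in% medical_categories()
  drop <- with_seed(seed, target & runif(nrow(ev)) < delta)
  registry$events <- ev[!drop]
  registry
}

#' Disadvantage indicator flags
#'
#' The four sensitive/protected attributes audited by the fairness module:
#' unmarried, immigrant, mental-health diagnosis, and pension below the
#' cohort median (persons without a defined pension — under 65 at the
#' reference date — count as not pension-disadvantaged). The `any` column
#' is their union.
#'
#' @param persons the persons table.
#' @return data.table with logical columns `unmarried`, `immigrant`,
#'   `mental_health_dx`, `low_pension`, `any`.
#' @export
disadvantage_flags <- function(persons) {
  med <- stats::median(persons$pension_level, na.rm = TRUE)
  fl <- data.table(
    person_id = persons$person_id,
    unmarried = persons$marital == "unmarried",
    immigrant = persons$immigrant,
    mental_health_dx = persons$mental_health_dx,
    low_pension = !is.na(persons$pension_level) &
      persons$pension_level < med
  )
  fl[, any := unmarried | immigrant | mental_health_dx | low_pension]
  fl[]
}
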