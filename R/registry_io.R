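#' Write a registry to three CSV files
#'
#' Writes `persons.csv`, `events.csv` and `deaths.csv` under `path` with the
#' documented headers, ISO-8601 dates, UTF-8 encoding and empty string for
#' missing values. Logical flags are serialized as 0/1. The latent `frailty`
#' column is written too (the synthetic registry is the only data source, and
#' the planted-signal recovery check needs the latent variable); consumers
#' modelling real data would simply not have that column.
#'
#' @param registry a registry.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  p <- copy(registry$persons)
  p[, immigrant := as.integer(immigrant)]
  p[, mental_health_dx := as.integer(mental_health_dx)]
  fwrite(p, file.path(path, "persons.csv"), na = "", dateTimeAs = "ISO")
  fwrite(registry$events, file.path(path, "events.csv"), na = "",
         dateTimeAs = "ISO")
  fwrite(registry$deaths, file.path(path, "deaths.csv"), na = "",
         dateTimeAs = "ISO")
  invisible(path)
}

#' @keywords internal
required_headers <- list(
  persons = c("person_id", "birth_date", "sex", "region", "pension_level",
              "marital", "immigrant", "mental_health_dx", "frailty",
              "emigrated_date"),
  events = c("person_id", "code", "category", "event_date"),
  deaths = c("person_id", "source", "death_year", "death_date")
)

#' Read a registry from three CSV files
#'
#' Inverse of [write_registry()]: validates headers and referential
#' integrity (events/deaths referencing unknown persons raise a parse error
#' naming the offending line).
#'
#' @param path directory containing `persons.csv`, `events.csv`,
#'   `deaths.csv`.
#' @return a `registry`.
#' @export
read_registry <- function(path) {
  rd <- function(name) {
    f <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    x <- fread(f, na.strings = "", colClasses = list(
      character = "person_id"))
    miss <- setdiff(required_headers[[name]], names(x))
    if (length(miss)) {
      stop(sprintf("malformed header in %s: missing column(s) %s",
                   f, paste(miss, collapse = ", ")), call. = FALSE)
    }
    x
  }
  persons <- rd("persons")
  events <- rd("events")
  deaths <- rd("deaths")
  for (cc in c("birth_date", "emigrated_date")) {
    persons[, (cc) := as.Date(get(cc))]
  }
  persons[, immigrant := as.logical(immigrant)]
  persons[, mental_health_dx := as.logical(mental_health_dx)]
  persons[, pension_level := as.numeric(pension_level)]
  if (nrow(events)) events[, event_date := as.Date(event_date)] else
    events <- empty_events()
  if (nrow(deaths)) {
    deaths[, death_date := as.Date(death_date)]
    deaths[, death_year := as.integer(death_year)]
    if (!"cod" %in% names(deaths)) deaths[, cod := NA_character_]
  } else deaths <- empty_deaths()
  reg <- new_registry(persons, events, deaths)
  # orphan check with line numbers (header is line 1)
  ids <- persons$person_id
  bad <- which(!(events$person_id %in% ids))
  if (length(bad)) {
    stop(sprintf("events.csv line %d: unknown person_id '%s'",
                 bad[1] + 1L, events$person_id[bad[1]]), call. = FALSE)
  }
  bad <- which(!(deaths$person_id %in% ids))
  if (length(bad)) {
    stop(sprintf("deaths.csv line %d: unknown person_id '%s'",
                 bad[1] + 1L, deaths$person_id[bad[1]]), call. = FALSE)
  }
  reg
}
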