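#' Randomly partition persons into train/validation/test
#'
#' Person-level, disjoint, exhaustive partition at the configured fractions,
#' with split sizes fixed by largest-remainder apportionment and membership
#' by a seeded permutation.
#'
#' @param persons persons table (or a registry).
#' @param spec a [split_spec()].
#' @param seed integer seed (default from spec).
#' @return named list of person_id character vectors
#'   (`train`, `valid`, `test`).
#' @export
assign_splits <- function(persons, spec = split_spec(), seed = spec$seed) {
  if (inherits(persons, "registry")) persons <- persons$persons
  ids <- persons$person_id
  n <- length(ids)
  sizes <- largest_remainder(n, spec$fractions)
  perm <- with_seed(seed, sample.int(max(n, 1L), n))
  shuffled <- ids[perm]
  out <- list(
    train = shuffled[seq_len(sizes[1])],
    valid = shuffled[seq_len(sizes[2]) + sizes[1]],
    test = shuffled[seq_len(sizes[3]) + sizes[1] + sizes[2]]
  )
  lapply(out, sort)
}

#' Apply inclusion/exclusion criteria to one split
#'
#' Excludes, in order and with one reason per person: (a) persons dead
#' before the split's predictive-interval start (union over both death
#' sources: a full-date record before the start, or a year-only record with
#' year before the interval's year), (b) persons emigrated before it, and
#' (c) persons with no register records of any kind, ever (these would be
#' unobservable, likely living abroad).
#'
#' @param registry a registry.
#' @param split_ids character vector of person_ids assigned to the split.
#' @param spec a [split_spec()].
#' @param split one of "train", "valid", "test".
#' @return list with `included` (character vector) and `tally` (named
#'   integer: died, emigrated, no_records, included).
#' @export
apply_inclusion_exclusion <- function(registry, split_ids, spec, split) {
  iv <- spec$splits[[split]]
  start <- iv$interval_start
  start_year <- as.integer(format(start, "%Y"))
  persons <- registry$persons[person_id %in% split_ids]
  de <- registry$deaths[person_id %in% split_ids]
  dead_b <- de[source == "B_full_date" & death_date < start, person_id]
  dead_a <- de[source == "A_year_only" & death_year < start_year, person_id]
  dead <- persons$person_id %in% union(dead_b, dead_a)
  emig <- !is.na(persons$emigrated_date) & persons$emigrated_date < start &
    !dead
  has_rec <- persons$person_id %in% unique(registry$events$person_id)
  norec <- !has_rec & !dead & !emig
  included <- persons$person_id[!(dead | emig | norec)]
  list(
    included = sort(included),
    tally = c(died = sum(dead), emigrated = sum(emig),
              no_records = sum(norec), included = length(included))
  )
}

#' Label one-year mortality outcomes for a cohort
#'
#' A person is a case (`label = 1`) if either death register puts the death
#' inside the split's predictive interval: the year-only source A records
#' the interval's year, or the full-date source B records a date within the
#' closed interval. `event_week` (1..52) comes from the source-B date when
#' that date falls in the interval; year-only cases fall back to week 26.
#' Controls are censored at week 52.
#'
#' @param registry a registry.
#' @param included character vector of included person_ids.
#' @param spec a [split_spec()].
#' @param split one of "train", "valid", "test".
#' @return data.table `cohort`: person_id, split, label, event_week
#'   (NA for controls), censored.
#' @export
label_outcomes <- function(registry, included, spec, split) {
  iv <- spec$splits[[split]]
  year <- as.integer(format(iv$interval_start, "%Y"))
  de <- registry$deaths[person_id %in% included]
  if (nrow(de)) {
    bd <- registry$persons[match(de$person_id, person_id), birth_date]
    if (any(!is.na(de$death_date) & de$death_date < bd)) {
      stop("death before birth: corrupt death record", call. = FALSE)
    }
  }
  case_a <- de[source == "A_year_only" & death_year == year, person_id]
  b_in <- de[source == "B_full_date" & !is.na(death_date) &
               death_date >= iv$interval_start &
               death_date <= iv$interval_end]
  cases <- union(case_a, b_in$person_id)
  wk <- setNames(rep(26L, length(cases)), cases)  # year-only fallback
  if (nrow(b_in)) wk[b_in$person_id] <- week_of_year(b_in$death_date)
  out <- data.table(
    person_id = included,
    split = split,
    label = as.integer(included %in% cases)
  )
  out[, event_week := ifelse(label == 1L, wk[person_id], NA_integer_)]
  out[, censored := label == 0L]
  out[]
}

#' Build the full three-split cohort table
#'
#' Convenience wrapper: assigns splits, applies inclusion/exclusion and
#' labels outcomes for each split.
#'
#' @param registry a registry.
#' @param spec a [split_spec()].
#' @param seed integer seed for the split assignment.
#' @return list with `cohort` (stacked data.table) and `tallies` (per-split
#'   exclusion tallies).
#' @export
build_cohort <- function(registry, spec = split_spec(), seed = spec$seed) {
  splits <- assign_splits(registry$persons, spec, seed)
  tallies <- list()
  parts <- lapply(names(splits), function(s) {
    ie <- apply_inclusion_exclusion(registry, splits[[s]], spec, s)
    tallies[[s]] <<- ie$tally
    label_outcomes(registry, ie$included, spec, s)
  })
  list(cohort = rbindlist(parts), tallies = tallies)
}
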