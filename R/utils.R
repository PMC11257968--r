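#' @useDynLib mortclock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats plogis qlogis rnorm runif rbinom rpois quantile sd glm
#'   binomial coef predict lm residuals as.formula setNames pnorm qnorm
#'   aggregate
#' @importFrom utils head tail
NULL

# data.table NSE columns referenced below; silences R CMD check notes
utils::globalVariables(c(
  "person_id", "code", "category", "event_date", "death_year", "death_date",
  "source", "birth_date", "sex", "age_year", "N", "split", "label",
  "event_week", "censored", "cod", "frailty", "emigrated_date",
  "pension_level", "immigrant", "mental_health_dx", "marital", "any",
  "pension", "low_pension", ".group", "combo", "deaths", "deaths_share",
  "group", "pct", "phi", "se", "stratum", "prevalence", "last_age_year",
  "first_age_year", "pix", "ay", "idx", "n_cases", "male", "score"
))

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministic fan-out of one global seed into named sub-stream seeds.
#' The scheme is a documented integer hash: the stage name's UTF-8 bytes are
#' folded with multiplier 31, combined with the global seed via multiplier
#' 1000003, reduced modulo 2^31 - 1 (so derived seeds stay valid 32-bit
#' R integers).
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2^31 - 1
  h <- 0
  for (b in as.integer(charToRaw(stage))) h <- (h * 31 + b) %% m
  as.integer((as.numeric(seed) %% m * 1000003 + h) %% m)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a field-naming validation error
#' @keywords internal
fail_field <- function(field, msg) {
  stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
}

#' Week of year on the 1..52 grid
#'
#' Weeks are `ceiling(day_of_year / 7)` capped at 52, so the last 1-2 days of
#' a year fall in week 52.
#'
#' @param date Date vector.
#' @return integer weeks in 1..52.
#' @export
week_of_year <- function(date) {
  doy <- as.POSIXlt(date)$yday + 1L
  pmin(as.integer(ceiling(doy / 7)), 52L)
}

#' Age in (fractional) years between two dates
#' @param birth,at Date vectors.
#' @return numeric years (365.25-day convention).
#' @export
age_years <- function(birth, at) as.numeric(at - birth) / 365.25

#' Largest-remainder apportionment
#'
#' Splits `n` into integer parts proportional to `fractions`, assigning
#' leftover units to the largest fractional remainders (ties broken by
#' position).
#'
#' @param n total count.
#' @param fractions numeric vector summing to 1.
#' @return integer vector summing to `n`.
#' @export
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- raw - base
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
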