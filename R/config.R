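#' Synthetic-registry generator configuration
#'
#' Bundles every knob of the synthetic registry: population composition,
#' per-category event processes, the discrete-time death hazard, planted
#' observation bias and death-register agreement. Defaults describe the world
#' the rest of the package assumes: an adult national-registry population with
#' roughly 1% annual mortality (1.02 cases per 100 controls), 50.8% females,
#' category-specific register start years (drug purchases 1995, outpatient
#' secondary care 1998, primary care 2011) and two death registers agreeing on
#' 99.83% of deaths.
#'
#' The annual death hazard for person \eqn{i} in calendar year \eqn{y} is
#' \deqn{logit h_{iy} = \beta_0 + \beta_{age}(age-70)/10 + \beta_{sex}[male]
#'   + \gamma f_i + \sum_k w_k e^{-\Delta t_k/\tau}}
#' where \eqn{f_i} is a standard-normal latent frailty and \eqn{\Delta t_k}
#' is the time in years since the most recent occurrence of risk code
#' \eqn{k} (the term is 0 if the code never occurred). `beta0`'s default was
#' calibrated once, by Monte Carlo integration over the default population,
#' so that the expected annual case fraction equals 1.02/101.02; it is not a
#' free parameter.
#'
#' Event counts per person-year and category are Poisson with
#' \eqn{\log \lambda_c = \log(base\_rate_c) + \alpha_c (age-40)/10 +
#' \gamma_{evt} f_i} (the frailty term applies to medical categories only);
#' codes are drawn Zipf(`zipf_s`) over the category vocabulary; no category
#' emits events before its register start year.
#'
#' @param n_persons number of persons to simulate.
#' @param birth_year_range length-2 integer vector of birth years (inclusive).
#' @param female_fraction probability of female sex (default 0.508).
#' @param category_specs named list of per-category lists with fields
#'   `vocabulary_size`, `base_rate` (events per person-year), `age_slope`
#'   (per-decade log-rate), `start_year` (calendar year the register starts).
#' @param risk_codes data.frame with columns `code`, `weight`: codes whose
#'   recent occurrence raises the death hazard.
#' @param hazard list with fields `beta0`, `beta_age` (per decade),
#'   `beta_sex` (male offset), `gamma` (frailty loading), `tau`
#'   (recency-decay time constant, years, > 0).
#' @param event_frailty frailty loading of medical event rates.
#' @param disadvantage_dropout probability delta that a medical event of a
#'   disadvantaged person is dropped by [apply_observation_bias()].
#' @param register_agreement probability rho that the year-only death register
#'   records the correct death year (default 0.9983).
#' @param emigration_fraction fraction of persons assigned an emigration date
#'   before any predictive interval.
#' @param zipf_s Zipf exponent for code draws within a category vocabulary.
#' @param reference_year calendar year used to decide pension eligibility
#'   (pension level is defined for persons aged 65+ on Jan 1 of this year).
#' @param seed integer default seed echoed into the registry.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_persons = 10000L,
                             birth_year_range = c(1925L, 2005L),
                             female_fraction = 0.508,
                             category_specs = default_category_specs(),
                             risk_codes = default_risk_codes(),
                             hazard = list(beta0 = -6.62, beta_age = 0.9,
                                           beta_sex = 0.5, gamma = 0.8,
                                           tau = 1.5),
                             event_frailty = 0.65,
                             disadvantage_dropout = 0.5,
                             register_agreement = 0.9983,
                             emigration_fraction = 0.03,
                             zipf_s = 1.1,
                             reference_year = 2020L,
                             seed = 1L) {
  cfg <- list(
    n_persons = as.integer(n_persons),
    birth_year_range = as.integer(birth_year_range),
    female_fraction = female_fraction,
    category_specs = category_specs,
    risk_codes = as.data.frame(risk_codes),
    hazard = hazard,
    event_frailty = event_frailty,
    disadvantage_dropout = disadvantage_dropout,
    register_agreement = register_agreement,
    emigration_fraction = emigration_fraction,
    zipf_s = zipf_s,
    reference_year = as.integer(reference_year),
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Default event-category specifications
#'
#' Five categories mirroring a Nordic registry stack: secondary (hospital)
#' diagnoses and surgical procedures from the outpatient register (start
#' 1998), drug purchases (1995), primary care (2011) and socioeconomic
#' records (1970). Rates are events per person-year at age 40 for a person
#' of average frailty.
#'
#' @return named list of category spec lists.
#' @export
default_category_specs <- function() {
  list(
    secondary_diagnosis = list(vocabulary_size = 150L, base_rate = 0.8,
                               age_slope = 0.25, start_year = 1998L),
    surgical_procedure  = list(vocabulary_size = 100L, base_rate = 0.15,
                               age_slope = 0.20, start_year = 1998L),
    drug_purchase       = list(vocabulary_size = 150L, base_rate = 2.0,
                               age_slope = 0.30, start_year = 1995L),
    primary_care        = list(vocabulary_size = 120L, base_rate = 1.0,
                               age_slope = 0.15, start_year = 2011L),
    socioeconomic       = list(vocabulary_size = 80L,  base_rate = 1.5,
                               age_slope = 0.00, start_year = 1970L)
  )
}

#' Default planted risk codes
#'
#' Six mid-frequency codes spread over the medical categories. Their recency
#' terms enter the death hazard with the given weights, so a model that reads
#' the longitudinal record can beat the age+sex baseline, and explainability
#' analyses have a known ranking to recover.
#'
#' @return data.frame with columns `code`, `weight`.
#' @export
default_risk_codes <- function() {
  data.frame(
    code = c("dx_0010", "dx_0020", "op_0005", "rx_0015", "rx_0030",
             "pc_0010"),
    weight = c(3.0, 2.6, 2.2, 1.8, 1.5, 1.2),
    stringsAsFactors = FALSE
  )
}

#' Category name to code-prefix mapping
#' @keywords internal
category_prefixes <- c(
  secondary_diagnosis = "dx", surgical_procedure = "op",
  drug_purchase = "rx", primary_care = "pc", socioeconomic = "se"
)

#' Medical (non-socioeconomic) categories
#' @keywords internal
medical_categories <- function() {
  c("secondary_diagnosis", "surgical_procedure", "drug_purchase",
    "primary_care")
}

#' Validate a generator configuration
#'
#' Errors name the offending field.
#'
#' @param cfg a `generator_config`.
#' @return the config, invisibly.
#' @export
validate_generator_config <- function(cfg) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      fail_field(nm, "must be a probability in [0, 1]")
    }
  }
  if (!is.numeric(cfg$n_persons) || length(cfg$n_persons) != 1 ||
      is.na(cfg$n_persons) || cfg$n_persons < 0) {
    fail_field("n_persons", "must be a non-negative count")
  }
  if (length(cfg$birth_year_range) != 2 ||
      cfg$birth_year_range[1] > cfg$birth_year_range[2]) {
    fail_field("birth_year_range", "must be an increasing pair of years")
  }
  chk_prob(cfg$female_fraction, "female_fraction")
  chk_prob(cfg$disadvantage_dropout, "disadvantage_dropout")
  chk_prob(cfg$register_agreement, "register_agreement")
  chk_prob(cfg$emigration_fraction, "emigration_fraction")
  if (!is.list(cfg$category_specs) || is.null(names(cfg$category_specs)) ||
      !all(names(cfg$category_specs) %in% names(category_prefixes))) {
    fail_field("category_specs", paste(
      "must be a named list over",
      paste(names(category_prefixes), collapse = ", ")))
  }
  for (nm in names(cfg$category_specs)) {
    sp <- cfg$category_specs[[nm]]
    if (is.null(sp$vocabulary_size) || sp$vocabulary_size < 1) {
      fail_field(paste0("category_specs$", nm, "$vocabulary_size"),
                 "must be >= 1")
    }
    if (is.null(sp$base_rate) || sp$base_rate < 0) {
      fail_field(paste0("category_specs$", nm, "$base_rate"),
                 "must be >= 0")
    }
    if (is.null(sp$start_year)) {
      fail_field(paste0("category_specs$", nm, "$start_year"), "missing")
    }
  }
  hz <- cfg$hazard
  for (nm in c("beta0", "beta_age", "beta_sex", "gamma", "tau")) {
    if (is.null(hz[[nm]]) || !is.numeric(hz[[nm]])) {
      fail_field(paste0("hazard$", nm), "must be numeric")
    }
  }
  if (hz$tau <= 0) fail_field("hazard$tau", "must be > 0")
  if (nrow(cfg$risk_codes) > 0 &&
      (!all(c("code", "weight") %in% names(cfg$risk_codes)))) {
    fail_field("risk_codes", "needs columns code, weight")
  }
  invisible(cfg)
}

#' Prospective split specification
#'
#' Defines the temporally-shifted train/validation/test design: persons are
#' split 70/10/20 at random, but each split has its own one-year predictive
#' interval, shifted one year later for validation and testing so those
#' outcome periods stay unseen during training. Features are usable only up
#' to a cutoff 3 months before each split's interval (the buffer guards
#' against outcome leakage).
#'
#' @param fractions train/validation/test fractions, must sum to 1.
#' @param train_year,valid_year,test_year calendar years of the three
#'   one-year predictive intervals (defaults 2018/2019/2020).
#' @param buffer_months buffer length in months (default 3).
#' @param seed integer seed for the random person-level partition.
#' @return object of class `split_spec`: per split, `feature_cutoff` (last
#'   usable feature date), `interval_start`, `interval_end`.
#' @export
split_spec <- function(fractions = c(train = 0.7, valid = 0.1, test = 0.2),
                       train_year = 2018L, valid_year = 2019L,
                       test_year = 2020L, buffer_months = 3L, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  years <- c(train = train_year, valid = valid_year, test = test_year)
  if (!(years["train"] < years["valid"] && years["valid"] < years["test"])) {
    stop("predictive intervals must shift strictly later for later splits",
         call. = FALSE)
  }
  splits <- lapply(years, function(y) {
    start <- as.Date(sprintf("%d-01-01", y))
    list(
      interval_start = start,
      interval_end = as.Date(sprintf("%d-12-31", y)),
      # last usable feature date: buffer_months before the interval start
      feature_cutoff = seq(start, by = paste0("-", buffer_months, " month"),
                           length.out = 2)[2] - 1
    )
  })
  structure(list(fractions = fractions, splits = splits,
                 buffer_months = as.integer(buffer_months),
                 seed = as.integer(seed)),
            class = "split_spec")
}
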