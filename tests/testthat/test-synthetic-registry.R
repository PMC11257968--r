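test_that("config validation names the offending field", {
  expect_error(generator_config(female_fraction = 1.7), "female_fraction")
  expect_error(generator_config(n_persons = -1), "n_persons")
  expect_error(generator_config(hazard = list(beta0 = 0, beta_age = 0,
                                              beta_sex = 0, gamma = 0,
                                              tau = 0)), "tau")
  cfg <- generator_config()
  cfg$category_specs$drug_purchase$vocabulary_size <- 0L
  expect_error(validate_generator_config(cfg), "vocabulary_size")
})

test_that("generate_population: empty case, determinism, sex fraction", {
  cfg <- tiny_config(0L)
  reg <- generate_population(cfg, seed = 1)
  expect_s3_class(reg, "registry")
  expect_equal(nrow(reg$persons), 0L)

  cfg2 <- tiny_config(10000L)
  r1 <- generate_population(cfg2, seed = 9)
  r2 <- generate_population(cfg2, seed = 9)
  expect_identical(r1$persons, r2$persons)

  # observed female fraction within 3 binomial SDs of 0.508
  f <- mean(r1$persons$sex == "female")
  expect_lt(abs(f - 0.508), 3 * sqrt(0.508 * 0.492 / 10000))

  expect_true(all(!duplicated(r1$persons$person_id)))
  expect_true(all(r1$persons$pension_level >= 0, na.rm = TRUE))
  # frailty ~ standard normal
  expect_lt(abs(mean(r1$persons$frailty)), 3 / sqrt(10000))
  expect_lt(abs(sd(r1$persons$frailty) - 1), 0.05)
  # emigration dates precede every predictive interval
  emig <- r1$persons$emigrated_date
  expect_true(all(emig < as.Date("2018-01-01"), na.rm = TRUE))
  expect_equal(sum(!is.na(emig)), round(0.03 * 10000))
})

test_that("simulate_events: null rates, start-year gating, Poisson mean", {
  cfg <- tiny_config(300L)
  for (nm in names(cfg$category_specs)) cfg$category_specs[[nm]]$base_rate <- 0
  reg <- generate_population(cfg, seed = 2)
  reg <- simulate_events(reg, cfg, 2020, seed = 3)
  expect_equal(nrow(reg$events), 0L)

  reg2 <- tiny_registry(800L, seed = 5)
  ev <- reg2$events
  specs <- reg2$config_echo$category_specs
  for (cat in names(specs)) {
    sub <- ev[category == cat]
    if (nrow(sub)) {
      expect_gte(min(as.integer(format(sub$event_date, "%Y"))),
                 specs[[cat]]$start_year)
    }
  }
  # drug purchases specifically never predate the 1995 register
  expect_equal(nrow(ev[category == "drug_purchase" &
                         event_date < as.Date("1995-01-01")]), 0L)
  # events never precede birth
  m <- merge(ev, reg2$persons[, .(person_id, birth_date)], by = "person_id")
  expect_true(all(m$event_date >= m$birth_date))

  # Poisson mean check: flat rate 2, no age slope, no frailty loading
  cfg3 <- generator_config(
    n_persons = 600L,
    category_specs = list(primary_care = list(vocabulary_size = 50L,
                                              base_rate = 2, age_slope = 0,
                                              start_year = 2012L)),
    risk_codes = data.frame(code = character(), weight = numeric()),
    event_frailty = 0)
  reg3 <- generate_population(cfg3, seed = 6)
  reg3 <- simulate_events(reg3, cfg3, 2020L, seed = 7)
  # persons born before 2012 contribute 9 full years each (2012..2020)
  old <- reg3$persons[format(birth_date, "%Y") < "2011"]
  ne <- reg3$events[person_id %in% old$person_id, .N]
  py <- nrow(old) * 9
  expect_lt(abs(ne / py - 2), 3 * sqrt(2 / py))
})

test_that("simulate_mortality: trivial hazards, calibration form, sources", {
  cfg <- tiny_config(400L)
  cfg$hazard$beta0 <- -Inf
  reg <- generate_population(cfg, seed = 8)
  reg <- simulate_events(reg, cfg, 2020, seed = 9)
  reg <- simulate_mortality(reg, cfg, 2018:2020, seed = 10)
  expect_equal(nrow(reg$deaths), 0L)

  # leakage guard: horizon beyond event simulation end
  expect_error(simulate_mortality(reg, cfg, 2018:2021, seed = 1),
               "leakage")

  # all covariates off, beta0 = logit(0.0102) -> death fraction matches
  cfg2 <- generator_config(
    n_persons = 20000L, birth_year_range = c(1950L, 1950L),
    hazard = list(beta0 = qlogis(0.0102), beta_age = 0, beta_sex = 0,
                  gamma = 0, tau = 2),
    risk_codes = data.frame(code = character(), weight = numeric()),
    emigration_fraction = 0)
  reg2 <- generate_population(cfg2, seed = 11)
  reg2 <- simulate_events(reg2, cfg2, 2018L, seed = 12)
  reg2 <- simulate_mortality(reg2, cfg2, 2018L, seed = 13)
  frac <- length(unique(reg2$deaths$person_id)) / 20000
  expect_lt(abs(frac - 0.0102), 3 * sqrt(0.0102 * 0.9898 / 20000))

  # rho = 1: sources agree on year for every death
  cfg3 <- tiny_config(3000L, register_agreement = 1)
  reg3 <- tiny_registry(3000L, seed = 14, cfg = cfg3)
  wide <- dcast(reg3$deaths, person_id ~ source, value.var = "death_year")
  expect_true(all(wide$A_year_only == wide$B_full_date))

  # B carries a full date, A only a year
  expect_true(all(!is.na(reg3$deaths[source == "B_full_date", death_date])))
  expect_true(all(is.na(reg3$deaths[source == "A_year_only", death_date])))

  # death weeks live on 1..52
  wk <- week_of_year(reg3$deaths[source == "B_full_date", death_date])
  expect_true(all(wk >= 1 & wk <= 52))

  # registers stop at death: no post-death events
  m <- merge(reg3$events,
             reg3$deaths[source == "B_full_date",
                         .(person_id, death_date)], by = "person_id")
  expect_true(all(m$event_date <= m$death_date))
})

test_that("register agreement rate matches rho", {
  cfg <- tiny_config(30000L, register_agreement = 0.9)
  reg <- tiny_registry(30000L, seed = 15, cfg = cfg)
  wide <- dcast(reg$deaths, person_id ~ source, value.var = "death_year")
  agree <- mean(wide$A_year_only == wide$B_full_date)
  n <- nrow(wide)
  expect_lt(abs(agree - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("apply_observation_bias: identity, total and binomial dropout", {
  reg <- tiny_registry(600L, seed = 16)
  mask <- rep(c(TRUE, FALSE), length.out = nrow(reg$persons))

  same <- apply_observation_bias(reg, reg$config_echo, mask, delta = 0,
                                 seed = 1)
  expect_identical(same$events, reg$events)

  gone <- apply_observation_bias(reg, reg$config_echo, mask, delta = 1,
                                 seed = 1)
  dis <- reg$persons$person_id[mask]
  left <- gone$events[person_id %in% dis &
                        category %in% mortclock:::medical_categories()]
  expect_equal(nrow(left), 0L)
  # socioeconomic records and deaths untouched
  expect_identical(gone$deaths, reg$deaths)
  expect_identical(gone$events[category == "socioeconomic"],
                   reg$events[category == "socioeconomic"])

  half <- apply_observation_bias(reg, reg$config_echo, mask, delta = 0.5,
                                 seed = 2)
  n0 <- nrow(reg$events[person_id %in% dis &
                          category %in% mortclock:::medical_categories()])
  n1 <- nrow(half$events[person_id %in% dis &
                           category %in% mortclock:::medical_categories()])
  expect_lt(abs(n1 / n0 - 0.5), 3 * sqrt(0.25 / n0))

  expect_error(apply_observation_bias(reg, reg$config_echo, mask[-1]),
               "mask length")
})

test_that("hazard coefficients are recoverable from the planted design", {
  # correctly specified logistic refit at modest n: coefficients land within
  # 3 SE (full-size version in test-acceptance.R)
  cfg <- tiny_config(12000L)
  reg <- tiny_registry(12000L, seed = 17, cfg = cfg)
  dB <- reg$deaths[source == "B_full_date"]
  cov <- hazard_covariates(reg, cfg, 2018)
  cov$y <- as.integer(cov$person_id %in% dB[death_year == 2018, person_id])
  rc_cols <- paste0("rc_", cfg$risk_codes$code)
  fml <- as.formula(paste("y ~ age10 + male + frailty +",
                          paste(rc_cols, collapse = "+")))
  fit <- glm(fml, data = cov, family = binomial())
  s <- summary(fit)$coefficients
  truth <- c(cfg$hazard$beta0, cfg$hazard$beta_age, cfg$hazard$beta_sex,
             cfg$hazard$gamma, cfg$risk_codes$weight)
  z <- (s[, 1] - truth) / s[, 2]
  expect_true(all(abs(z) < 4))  # modest-n smoke; acceptance uses n=50k, 3 SE
})
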