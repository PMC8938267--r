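test_that("identical config and seed reproduce a byte-identical cohort", {
  cfg <- sim_config(n_exposed = 300, n_contemporary = 500, n_historical = 200,
                    n_noise_codes_per_domain = c(10, 10, 5), seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  d <- generate_cohort(sim_config(n_exposed = 300, n_contemporary = 500,
                                  n_historical = 200,
                                  n_noise_codes_per_domain = c(10, 10, 5),
                                  seed = 12L))
  expect_false(identical(a$persons$t0, d$persons$t0))
})

test_that("zero death hazard yields no death dates", {
  cfg <- sim_config(n_exposed = 200, n_contemporary = 300, n_historical = 0,
                    death_hazard = 0, n_noise_codes_per_domain = c(0, 0, 0),
                    true_log_hr = c(stroke = 0),
                    baseline_hazard = c(stroke = 1e-4), seed = 4L)
  coh <- generate_cohort(cfg)
  expect_true(all(is.na(coh$persons$death_date)))
})

test_that("null config produces equal outcome rates across groups", {
  cfg <- sim_config(n_exposed = 4000, n_contemporary = 4000, n_historical = 0,
                    n_confounders = 0,
                    confounder_effect_on_exposure = numeric(0),
                    confounder_effect_on_hazard = numeric(0),
                    true_log_hr = c(stroke = 0), death_hazard = 0,
                    baseline_hazard = c(stroke = 3e-4),
                    n_noise_codes_per_domain = c(0, 0, 0), seed = 8L)
  coh <- assign_t0(generate_cohort(cfg), cohort_spec(), seed = 9L)
  lm <- apply_landmark(coh, cohort_spec())
  sc <- build_subcohort(lm, "stroke", cohort_spec())
  rate <- tapply(sc$event, sc$group, sum) / tapply(sc$time, sc$group, sum)
  # two-sample Poisson-rate z-test; should not reject the configured null
  z <- (log(rate[["exposed"]]) - log(rate[["contemporary"]])) /
    sqrt(1 / sum(sc$event[sc$group == "exposed"]) +
         1 / sum(sc$event[sc$group == "contemporary"]))
  expect_lt(abs(z), 3)
})

test_that("crude rate ratio recovers exp(beta) without confounding", {
  beta <- log(1.8)
  cfg <- sim_config(n_exposed = 20000, n_contemporary = 20000,
                    n_historical = 0, n_confounders = 0,
                    confounder_effect_on_exposure = numeric(0),
                    confounder_effect_on_hazard = numeric(0),
                    true_log_hr = c(stroke = beta), death_hazard = 0,
                    baseline_hazard = c(stroke = 2e-4),
                    n_noise_codes_per_domain = c(0, 0, 0), seed = 21L)
  coh <- assign_t0(generate_cohort(cfg), cohort_spec(), seed = 22L)
  lm <- apply_landmark(coh, cohort_spec())
  sc <- build_subcohort(lm, "stroke", cohort_spec())
  ev <- tapply(sc$event, sc$group, sum)
  pt <- tapply(sc$time, sc$group, sum)
  # closed-form exponential MLE of the rate ratio and its log-scale SE
  log_rr <- log((ev[["exposed"]] / pt[["exposed"]]) /
                (ev[["contemporary"]] / pt[["contemporary"]]))
  se <- sqrt(1 / ev[["exposed"]] + 1 / ev[["contemporary"]])
  expect_lt(abs(log_rr - beta), 3 * se)
})

test_that("12-month cumulative incidence matches 1 - exp(-h*365) without competing risk", {
  h <- 3e-4
  cfg <- sim_config(n_exposed = 20000, n_contemporary = 1, n_historical = 0,
                    n_confounders = 0,
                    confounder_effect_on_exposure = numeric(0),
                    confounder_effect_on_hazard = numeric(0),
                    true_log_hr = c(stroke = 0), death_hazard = 0,
                    baseline_hazard = c(stroke = h),
                    n_noise_codes_per_domain = c(0, 0, 0),
                    enrollment_dates = as.Date("2020-04-01"),
                    seed = 31L)
  coh <- generate_cohort(cfg)
  p <- coh$persons[coh$persons$group == "exposed", ]
  ev <- coh$events[match(p$person_id, coh$events$person_id), "date"]
  # condition on being event-free at T0 (incident-analysis population);
  # residual time is exponential by memorylessness
  at_risk <- is.na(ev) | ev > p$t0
  inside <- !is.na(ev) & ev > p$t0 & ev <= p$t0 + 365
  expected <- 1 - exp(-h * 365)
  se <- sqrt(expected * (1 - expected) / sum(at_risk))
  expect_lt(abs(mean(inside[at_risk]) - expected), 3 * se)
})

test_that("inject_history flags an exact seeded count and respects bounds", {
  cfg <- sim_config(n_exposed = 1000, n_contemporary = 10, n_historical = 0,
                    true_log_hr = c(stroke = 0), death_hazard = 0,
                    baseline_hazard = c(stroke = 1e-6),
                    n_noise_codes_per_domain = c(0, 0, 0), seed = 41L)
  coh <- assign_t0(generate_cohort(cfg), cohort_spec(), seed = 42L)
  before <- coh$events
  expect_identical(inject_history(coh, "stroke", 0, seed = 1)$events, before)
  coh2 <- inject_history(coh, "stroke", 0.3, seed = 1)
  p <- coh2$persons
  ev <- coh2$events[coh2$events$outcome == "stroke", ]
  t0 <- p$t0[match(ev$person_id, p$person_id)]
  pre <- ev$date >= t0 - 365 & ev$date < t0
  expect_equal(sum(pre), round(0.3 * nrow(p)))
  # fraction 1: every person carries pre-T0 history and is excluded later
  coh3 <- inject_history(coh, "stroke", 1, seed = 1)
  lm <- apply_landmark(coh3, cohort_spec())
  sc <- build_subcohort(lm, "stroke", cohort_spec())
  expect_equal(nrow(sc), 0L)
  expect_error(inject_history(coh, "nonexistent", 0.5), "unknown outcome")
})

test_that("configuration errors are rejected", {
  expect_error(sim_config(n_exposed = 0), "positive")
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
  expect_error(sim_config(care_setting_probs = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(sim_config(baseline_hazard = c(stroke = -1)), "outcomes|>= 0")
})

test_that("cohort round-trips through delimited text", {
  cfg <- sim_config(n_exposed = 100, n_contemporary = 150, n_historical = 80,
                    n_noise_codes_per_domain = c(5, 5, 2), seed = 13L)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$persons$t0, coh$persons$t0)
  expect_equal(back$persons$age, coh$persons$age)
  expect_equal(nrow(back$events), nrow(coh$events))
  expect_equal(back$config$seed, cfg$seed)
})
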