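sim_exp_subcohort <- function(n_per_group, rate_control, rate_ratio,
                              death_rate = 0, admin = 500, seed = 1) {
  set.seed(seed)
  grp <- rep(c("exposed", "control"), each = n_per_group)
  rate <- ifelse(grp == "exposed", rate_control * rate_ratio, rate_control)
  te <- rexp(2 * n_per_group, rate)
  td <- if (death_rate > 0) rexp(2 * n_per_group, death_rate) else Inf
  t <- pmin(te, td, admin)
  as_subcohort(data.frame(
    person_id = seq_along(grp), group = grp,
    time = t, event = as.integer(te <= pmin(td, admin)),
    death = as.integer(td < pmin(te, admin))))
}

test_that("weighted Cox recovers the null and a known rate ratio", {
  sc <- sim_exp_subcohort(3000, 2e-3, 1, seed = 3)
  hz <- fit_weighted_cox(sc, exposed_level = "exposed")
  expect_false(hz$significant)
  expect_true(hz$ci95[1] < 1 && hz$ci95[2] > 1)

  sc2 <- sim_exp_subcohort(5000, 1e-3, 2, seed = 4)
  hz2 <- fit_weighted_cox(sc2, exposed_level = "exposed")
  # closed-form exponential MLE oracle: event-count / person-time ratio
  ev <- tapply(sc2$event, sc2$group, sum)
  pt <- tapply(sc2$time, sc2$group, sum)
  mle <- (ev[["exposed"]] / pt[["exposed"]]) / (ev[["control"]] / pt[["control"]])
  expect_equal(hz2$log_hr, log(mle), tolerance = 0.02)
  expect_true(hz2$ci95[1] < 2 && 2 < hz2$ci95[2])
})

test_that("constant rescaling of the weights leaves the HR unchanged", {
  sc <- sim_exp_subcohort(800, 2e-3, 1.5, seed = 5)
  h1 <- fit_weighted_cox(sc, weights = rep(1, nrow(sc)),
                         exposed_level = "exposed")
  h2 <- fit_weighted_cox(sc, weights = rep(3.7, nrow(sc)),
                         exposed_level = "exposed")
  expect_equal(h1$log_hr, h2$log_hr, tolerance = 1e-8)
})

test_that("a group without events is reported, not silently fit", {
  sc <- as_subcohort(data.frame(person_id = 1:4,
                                group = rep(c("exposed", "control"), 2),
                                time = c(10, 20, 30, 40),
                                event = c(1L, 0L, 1L, 0L)))
  expect_error(fit_weighted_cox(sc, exposed_level = "exposed"),
               "no events in the control")
})

test_that("cumulative incidence matches competing-exponential closed forms", {
  h1 <- 4e-4; h2 <- 2e-4; n <- 40000
  set.seed(11)
  te <- rexp(n, h1); td <- rexp(n, h2); admin <- 400
  t <- pmin(te, td, admin)
  sc <- as_subcohort(data.frame(
    person_id = 1:n, group = "exposed", time = t,
    event = as.integer(te <= pmin(td, admin)),
    death = as.integer(td < pmin(te, admin))))
  cif <- estimate_cif(sc, horizon_days = 365)
  truth <- 1000 * cif_closed_form(h1, h2, 365)
  se <- 1000 * sqrt(truth / 1000 * (1 - truth / 1000) / n)
  expect_lt(abs(cif$burden - truth), 3 * se)

  # without competing deaths the closed form is 1 - exp(-h*365)
  scn <- as_subcohort(data.frame(
    person_id = 1:n, group = "exposed", time = pmin(te, admin),
    event = as.integer(te <= admin), death = 0L))
  cifn <- estimate_cif(scn, horizon_days = 365)
  truthn <- 1000 * (1 - exp(-h1 * 365))
  sen <- 1000 * sqrt(truthn / 1000 * (1 - truthn / 1000) / n)
  expect_lt(abs(cifn$burden - truthn), 3 * sen)

  expect_error(estimate_cif(sc, horizon_days = 1e5), "exceeds all follow-up")
})

test_that("weighted Aalen-Johansen matches the hand-stepped recursion", {
  t <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 10)
  st <- c(1, 0, 2, 1, 0, 1, 2, 0, 1, 0)
  w <- c(1, 2, 1, 1, 3, 1, 2, 1, 1, 2)
  sc <- as_subcohort(data.frame(person_id = 1:10, group = "g", time = t,
                                event = as.integer(st == 1),
                                death = as.integer(st == 2)))
  cif <- estimate_cif(sc, weights = w, horizon_days = 10)
  # frozen value from an independent hand recursion over the risk sets
  expect_equal(cif$burden, 1000 * 0.4080808, tolerance = 1e-6)
})

test_that("with no deaths the AJ estimator equals 1 - Kaplan-Meier exactly", {
  set.seed(21)
  t <- rexp(200, 0.01); ev <- rbinom(200, 1, 0.7)
  sc <- as_subcohort(data.frame(person_id = 1:200, group = "g", time = t,
                                event = ev, death = 0L))
  cif <- estimate_cif(sc, horizon_days = 50)
  km <- survival::survfit(survival::Surv(t, ev) ~ 1)
  skm <- summary(km, times = 50, extend = TRUE)$surv
  expect_equal(cif$burden, 1000 * (1 - skm), tolerance = 1e-10)
})

test_that("unweighted AJ agrees with an independent competing-risk estimator", {
  set.seed(22)
  n <- 500
  te <- rexp(n, 3e-3); td <- rexp(n, 2e-3); t <- pmin(te, td, 600)
  status <- ifelse(te <= pmin(td, 600), 1, ifelse(td < 600, 2, 0))
  sc <- as_subcohort(data.frame(person_id = 1:n, group = "g", time = t,
                                event = as.integer(status == 1),
                                death = as.integer(status == 2)))
  cif <- estimate_cif(sc, horizon_days = 365)
  ref <- cmprsk::cuminc(t, status, cencode = 0)
  ref_est <- cmprsk::timepoints(ref, 365)$est["1 1", 1]
  expect_equal(cif$burden, 1000 * ref_est, tolerance = 1e-8)
})

test_that("excess burden is the exact difference with a sensible bootstrap CI", {
  sc <- sim_exp_subcohort(4000, 3e-4, 2, death_rate = 2e-4, seed = 31)
  eb <- excess_burden(sc, resamples = 200, seed = 9)
  cif <- estimate_cif(sc, horizon_days = 365)
  expect_equal(eb$excess_burden,
               cif$burden[cif$group == "exposed"] -
                 cif$burden[cif$group == "control"])
  truth <- 1000 * (cif_closed_form(6e-4, 2e-4, 365) -
                   cif_closed_form(3e-4, 2e-4, 365))
  expect_true(eb$excess_burden_ci95[1] < truth &&
              truth < eb$excess_burden_ci95[2])

  # identical groups: excess near zero, CI covers zero
  scn <- sim_exp_subcohort(3000, 3e-4, 1, seed = 32)
  ebn <- excess_burden(scn, resamples = 200, seed = 9)
  expect_true(ebn$excess_burden_ci95[1] < 0 && 0 < ebn$excess_burden_ci95[2])
  expect_error(excess_burden(sc, resamples = 1), "resamples")
})

test_that("censoring at external event dates truncates person-time correctly", {
  entry <- as.Date("2020-05-01")
  sc <- as_subcohort(data.frame(person_id = 1:4, group = "exposed",
                                entry_date = entry,
                                time = c(100, 200, 300, 50),
                                event = c(1L, 1L, 0L, 0L)))
  expect_identical(censor_at(sc, setNames(as.Date(character(0)),
                                          character(0)))$time, sc$time)
  dates <- setNames(entry + c(50, 250, -10), c("1", "2", "3"))
  expect_warning(out <- censor_at(sc, dates), "dropped")
  # person 1: censored at day 50, event wiped; person 2: event at 200 < 250
  # stands; person 3 dropped (censor before entry); person 4 untouched
  expect_equal(out$time, c(50, 200, 50))
  expect_equal(out$event, c(0L, 1L, 0L))
  expect_equal(attr(out, "dropped"), 1L)
  expect_equal(sum(out$time), 300)  # hand-computed person-time
})

test_that("time-varying vaccination model degenerates correctly", {
  sc <- sim_exp_subcohort(1500, 1e-3, 1.6, seed = 41)
  sc$entry_date <- as.Date("2020-05-01")
  none <- setNames(as.Date(character(0)), character(0))
  base <- fit_weighted_cox(sc, exposed_level = "exposed")
  tv0 <- fit_time_varying(sc, tv_covariate_dates = none,
                          exposed_level = "exposed")
  expect_equal(tv0$log_hr, base$log_hr, tolerance = 1e-8)
  expect_true(tv0$aliased)  # indicator never varies -> no information

  # everyone switched at entry: aliased with the baseline
  all_on <- setNames(rep(sc$entry_date[1] - 1, nrow(sc)),
                     as.character(sc$person_id))
  tv1 <- fit_time_varying(sc, tv_covariate_dates = all_on,
                          exposed_level = "exposed")
  expect_true(tv1$aliased)
})

test_that("episode splitting reproduces hand-enumerated risk intervals", {
  entry <- as.Date("2020-05-01")
  sc <- as_subcohort(data.frame(person_id = 1:6, group = rep(c("exposed", "control"), 3),
                                entry_date = entry,
                                time = c(100, 120, 60, 90, 40, 70),
                                event = c(1L, 0L, 1L, 1L, 0L, 1L)))
  dates <- setNames(entry + c(30, 130, 10), c("1", "2", "5"))
  tv <- fit_time_varying(sc, tv_covariate_dates = dates,
                         exposed_level = "exposed")
  long <- tv$model$y  # (tstart, tstop, status] intervals seen by the model
  m <- as.matrix(long)
  # hand enumeration: person 1 -> (0,30,0)+(30,100,1); person 2 -> (0,120,0)
  # (switch at 130 is after exit); person 5 -> (0,10,0)+(10,40,0); others whole
  expect_equal(nrow(m), 8L)
  expect_true(any(m[, 1] == 30 & m[, 2] == 100 & m[, 3] == 1))
  expect_true(any(m[, 1] == 0 & m[, 2] == 30 & m[, 3] == 0))
  expect_true(any(m[, 1] == 10 & m[, 2] == 40 & m[, 3] == 0))
  expect_false(tv$aliased)
})
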