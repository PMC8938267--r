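test_that("control T0 assignment mirrors the exposed date distribution", {
  one <- as.Date("2020-03-15")
  t0 <- assign_control_t0(rep(one, 5), 1:20, offset_days = 0, seed = 1)
  expect_true(all(t0 == one))
  t0h <- assign_control_t0(rep(one, 5), 1:20, offset_days = 730, seed = 1)
  expect_true(all(t0h == as.Date("2018-03-16")))  # exact 730-day arithmetic

  two <- as.Date(c("2020-04-01", "2020-11-01"))
  draws <- assign_control_t0(rep(two, each = 50), 1:10000, 0, seed = 3)
  frac <- mean(draws == two[1])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))

  expect_error(assign_control_t0(as.Date(character(0)), 1:3), "non-empty")
  expect_error(assign_control_t0(two, integer(0)), "non-empty")
})

test_that("landmark filter requires survival strictly beyond day 30", {
  t0 <- as.Date("2020-05-01")
  persons <- data.frame(
    person_id = 1:4, group = "exposed", t0 = t0,
    death_date = c(t0 + 10, t0 + 30, t0 + 31, as.Date(NA)))
  coh <- fixture_cohort(persons)
  out <- apply_landmark(coh, cohort_spec())
  expect_setequal(out$persons$person_id, c(3L, 4L))
  expect_equal(unname(attr(out, "exclusions")["died_before_landmark"]), 2)
  expect_true(all(out$persons$entry_date == t0 + 30))

  persons$t0[1] <- as.Date(NA)
  expect_error(apply_landmark(fixture_cohort(persons), cohort_spec()),
               "assign_t0")
})

test_that("subcohort construction matches manual enumeration on a handcrafted table", {
  t0 <- as.Date("2020-06-01")
  eof <- as.Date("2021-10-31")
  # 8 persons covering every exclusion and censoring branch
  persons <- data.frame(
    person_id = 1:8,
    group = c("exposed", "exposed", "exposed", "exposed",
              "contemporary", "contemporary", "contemporary", "contemporary"),
    t0 = t0,
    death_date = c(rep(as.Date(NA), 6), t0 + 200, as.Date(NA)))
  events <- data.frame(
    person_id = c(1L, 2L, 3L, 5L, 6L),
    outcome = "stroke",
    date = c(t0 - 100,        # 1: history -> excluded
             t0 + 10,         # 2: acute window -> excluded (default)
             t0 + 90,         # 3: incident event at day 60 after entry
             t0 + 31,         # 5: incident event at day 1 after entry
             t0 - 400))       # 6: old occurrence outside lookback -> kept, no event
  coh <- fixture_cohort(persons, events)
  lm <- apply_landmark(coh, cohort_spec())
  sc <- build_subcohort(lm, "stroke", cohort_spec())

  expect_setequal(sc$person_id, c(3L, 4L, 5L, 6L, 7L, 8L))
  get <- function(id, col) sc[sc$person_id == id, col]
  expect_equal(get(3L, "time"), 60)            # event at t0+90, entry t0+30
  expect_equal(get(3L, "event"), 1L)
  expect_equal(get(5L, "time"), 1)
  expect_equal(get(4L, "time"), as.numeric(eof - (t0 + 30)))
  expect_equal(get(4L, "event"), 0L)
  expect_equal(get(7L, "time"), 170)           # death censors at t0+200
  expect_equal(get(7L, "death"), 1L)
  expect_equal(unname(attr(sc, "exclusions")["history"]), 1)
  expect_equal(unname(attr(sc, "exclusions")["acute_window"]), 1)

  # "ignore" flag retains acute-window persons event-free
  sc2 <- build_subcohort(lm, "stroke", cohort_spec(acute_events = "ignore"))
  expect_true(2L %in% sc2$person_id)
  expect_equal(sc2[sc2$person_id == 2L, "event"], 0L)

  expect_error(build_subcohort(lm, "no_such_outcome", cohort_spec()),
               "unknown outcome")
})

test_that("MACE composite treats death as an event, not a competing risk", {
  t0 <- as.Date("2020-06-01")
  persons <- data.frame(
    person_id = 1:3,
    group = c("exposed", "exposed", "contemporary"),
    t0 = t0,
    death_date = c(t0 + 100, as.Date(NA), as.Date(NA)))
  events <- data.frame(person_id = 2L, outcome = "myocardial_infarction",
                       date = t0 + 50)
  coh <- fixture_cohort(persons, events)
  lm <- apply_landmark(coh, cohort_spec())
  sc <- build_subcohort(lm, "mace", cohort_spec())
  get <- function(id, col) sc[sc$person_id == id, col]
  expect_equal(get(1L, "event"), 1L)   # death itself is the event
  expect_equal(get(1L, "time"), 70)
  expect_equal(get(2L, "event"), 1L)   # component event
  expect_equal(get(2L, "time"), 20)
  expect_true(all(sc$death == 0L))     # no competing-risk channel for MACE
})

test_that("care-setting strata partition the exposed cohort", {
  lm <- small_landmarked()
  sc <- build_subcohort(lm, "stroke", cohort_spec())
  exp_rows <- sc[sc$group == "exposed", ]
  strata <- table(exp_rows$care_setting)
  expect_equal(sum(strata[c("non_hospitalized", "hospitalized", "icu")]),
               nrow(exp_rows))
})

test_that("longer lookback never enlarges the subcohort", {
  lm <- small_landmarked()
  sizes <- vapply(c(90L, 180L, 365L, 720L), function(lb) {
    nrow(build_subcohort(lm, "stroke", cohort_spec(lookback_days = lb)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
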