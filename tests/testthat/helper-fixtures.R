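# Shared fixtures: built in code, cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# small three-group cohort with confounding and a real effect on stroke
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(n_exposed = 2000, n_contemporary = 4000,
                      n_historical = 2500,
                      n_noise_codes_per_domain = c(30, 30, 10),
                      n_signal_codes_per_domain = c(5, 5, 2),
                      baseline_hazard = c(stroke = 2e-4,
                                          myocardial_infarction = 1.5e-4),
                      true_log_hr = c(stroke = log(1.7),
                                      myocardial_infarction = 0,
                                      death = log(1.5)),
                      seed = 2024L)
    .fixture_env$small <- generate_cohort(cfg)
  }
  .fixture_env$small
}

small_landmarked <- function() {
  if (is.null(.fixture_env$small_lm)) {
    coh <- assign_t0(small_cohort(), cohort_spec(), seed = 77L)
    .fixture_env$small_lm <- apply_landmark(coh, cohort_spec())
  }
  .fixture_env$small_lm
}

# wrap a plain data frame as a subcohort for the survival functions
as_subcohort <- function(df, outcome = "toy") {
  if (is.null(df$care_setting)) df$care_setting <- "none"
  if (is.null(df$entry_date)) df$entry_date <- as.Date("2020-04-01")
  if (is.null(df$death)) df$death <- 0L
  df$group <- factor(df$group)
  structure(df, class = c("pa_subcohort", "data.frame"), outcome = outcome)
}

# minimal hand-built cohort for cohort-builder fixtures
fixture_cohort <- function(persons, events = NULL, codes = NULL) {
  if (is.null(events))
    events <- data.frame(person_id = integer(0), outcome = character(0),
                         date = as.Date(character(0)))
  if (is.null(codes))
    codes <- data.frame(person_id = integer(0), domain = character(0),
                        code = character(0), date = as.Date(character(0)))
  persons$group <- factor(persons$group,
                          levels = c("exposed", "contemporary", "historical"))
  if (is.null(persons$care_setting)) persons$care_setting <- "none"
  if (is.null(persons$death_date)) persons$death_date <- as.Date(NA)
  structure(list(persons = persons, events = events, codes = codes,
                 config = NULL),
            class = "pa_cohort", data_start = as.Date("2017-01-01"))
}

# closed-form competing-exponentials CIF
cif_closed_form <- function(h1, h2, t) h1 / (h1 + h2) * (1 - exp(-(h1 + h2) * t))
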