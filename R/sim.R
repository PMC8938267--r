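#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates the parameters that drive [generate_cohort()].
#' The generator emulates the statistical structure of a large
#' electronic-health-record study of post-acute outcomes: an exposed group
#' enrolled over a calendar window, a contemporary control group drawn from
#' the same era, a historical control group observed two years earlier,
#' shared confounders that shift both the probability of exposure and the
#' cause-specific event hazards, sparse high-dimensional code occurrences
#' in three domains (diagnoses, medications, laboratory abnormalities),
#' death as a competing risk, care-setting strata of the acute phase with
#' optionally graded effect sizes, and vaccination dates.
#'
#' Event times follow piecewise-constant (exponential) cause-specific
#' hazards: every person carries a calendar-time event clock starting one
#' year before the enrollment window (shifted back a further
#' `historical_offset_days` for the historical group) at unexposed rates;
#' exposed persons switch to exposure-multiplied rates at their T0. The
#' memoryless property makes residual post-T0 event times exactly
#' exponential, so closed-form oracles apply, while pre-T0 occurrences
#' arise organically and exercise the history-exclusion logic downstream.
#'
#' Baseline event rates are not dictated by any published source for this
#' kind of cohort and the defaults here are arbitrary desk-scale choices
#' (roughly 0.5--1 events per 100 person-years for the named outcomes,
#' 3 deaths per 100 person-years); set them to suit the study at hand.
#'
#' @param n_exposed,n_contemporary,n_historical group sizes (positive).
#' @param enrollment_dates `Date` vector of possible exposed index dates.
#' @param enrollment_probs sampling probabilities for `enrollment_dates`
#'   (recycled uniform when `NULL`).
#' @param care_setting_probs length-3 probability vector over
#'   non-hospitalized, hospitalized and ICU care during the acute phase;
#'   must sum to 1.
#' @param n_confounders number of shared standard-normal confounders.
#' @param confounder_effect_on_exposure,confounder_effect_on_hazard numeric
#'   vectors of length `n_confounders`: log-odds coefficients on the
#'   exposure logit and log-hazard coefficients shared by all causes.
#' @param true_log_hr named numeric vector of exposure log hazard ratios,
#'   one per outcome; a `"death"` entry sets the exposure effect on the
#'   competing death hazard (0 when absent).
#' @param care_setting_log_hr optional named list mapping an outcome to a
#'   length-3 vector of care-setting-specific log HRs (non-hospitalized,
#'   hospitalized, ICU) overriding `true_log_hr` for exposed persons.
#' @param baseline_hazard named numeric vector of per-day baseline rates,
#'   same names as the outcome entries of `true_log_hr`.
#' @param death_hazard per-day baseline death rate.
#' @param n_noise_codes_per_domain integer vector of code counts for the
#'   diagnosis, medication and laboratory domains.
#' @param n_signal_codes_per_domain codes per domain whose prevalence is
#'   linked to the confounders (so high-dimensional selection has signal
#'   to find).
#' @param missing_rate MCAR missingness fraction applied to the continuous
#'   clinical covariates.
#' @param vaccination_rate fraction of exposed/contemporary persons with a
#'   vaccination date.
#' @param history_days calendar depth of the observable pre-enrollment
#'   record: event clocks start this many days before the enrollment
#'   window. Three years by default, enough to observe the matched
#'   pre-exposure period of the difference-in-differences design plus
#'   its one-year history lookback.
#' @param admin_censor_date administrative end of the simulated calendar
#'   window for the exposed and contemporary groups (shifted back
#'   `historical_offset_days` for the historical group).
#' @param historical_offset_days calendar shift of the historical group.
#' @param seed integer seed; identical config (including seed) yields a
#'   byte-identical cohort.
#'
#' @return an object of class `pa_sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_exposed = 5000,
                       n_contemporary = 15000,
                       n_historical = 15000,
                       enrollment_dates = seq(as.Date("2020-03-01"),
                                              as.Date("2021-01-15"), by = "day"),
                       enrollment_probs = NULL,
                       care_setting_probs = c(0.856, 0.109, 0.035),
                       n_confounders = 3,
                       confounder_effect_on_exposure = rep(0.5, n_confounders),
                       confounder_effect_on_hazard = rep(0.3, n_confounders),
                       true_log_hr = c(stroke = log(1.5),
                                       myocardial_infarction = log(1.6),
                                       death = log(1.6)),
                       care_setting_log_hr = NULL,
                       baseline_hazard = c(stroke = 2e-05,
                                           myocardial_infarction = 1.5e-05),
                       death_hazard = 8e-05,
                       n_noise_codes_per_domain = c(540, 543, 62),
                       n_signal_codes_per_domain = c(5, 5, 2),
                       missing_rate = 0.05,
                       vaccination_rate = 0.4,
                       history_days = 1095L,
                       admin_censor_date = as.Date("2021-10-31"),
                       historical_offset_days = 730,
                       seed = 1L) {
  cfg <- list(n_exposed = as.integer(n_exposed),
              n_contemporary = as.integer(n_contemporary),
              n_historical = as.integer(n_historical),
              enrollment_dates = as.Date(enrollment_dates),
              enrollment_probs = enrollment_probs,
              care_setting_probs = care_setting_probs,
              n_confounders = as.integer(n_confounders),
              confounder_effect_on_exposure = confounder_effect_on_exposure,
              confounder_effect_on_hazard = confounder_effect_on_hazard,
              true_log_hr = true_log_hr,
              care_setting_log_hr = care_setting_log_hr,
              baseline_hazard = baseline_hazard,
              death_hazard = death_hazard,
              n_noise_codes_per_domain = as.integer(n_noise_codes_per_domain),
              n_signal_codes_per_domain = as.integer(n_signal_codes_per_domain),
              missing_rate = missing_rate,
              vaccination_rate = vaccination_rate,
              history_days = as.integer(history_days),
              admin_censor_date = as.Date(admin_censor_date),
              historical_offset_days = as.integer(historical_offset_days),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "pa_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_exposed <= 0 || n_contemporary < 0 || n_historical < 0 ||
        n_contemporary + n_historical <= 0)
      stop("group sizes must be positive (control groups may be 0 ",
           "individually but not jointly)", call. = FALSE)
    if (length(enrollment_dates) < 1L)
      stop("enrollment_dates must be non-empty", call. = FALSE)
    if (!is.null(enrollment_probs)) {
      if (length(enrollment_probs) != length(enrollment_dates) ||
          any(enrollment_probs < 0) || abs(sum(enrollment_probs) - 1) > 1e-8)
        stop("enrollment_probs must be a probability vector over enrollment_dates",
             call. = FALSE)
    }
    if (length(care_setting_probs) != 3L || any(care_setting_probs < 0) ||
        any(care_setting_probs > 1) || abs(sum(care_setting_probs) - 1) > 1e-8)
      stop("care_setting_probs must be 3 probabilities summing to 1", call. = FALSE)
    if (n_confounders < 0)
      stop("n_confounders must be >= 0", call. = FALSE)
    if (length(confounder_effect_on_exposure) != n_confounders ||
        length(confounder_effect_on_hazard) != n_confounders)
      stop("confounder effect vectors must have length n_confounders", call. = FALSE)
    outs <- setdiff(names(true_log_hr), "death")
    if (length(outs) == 0L || is.null(names(baseline_hazard)) ||
        !setequal(outs, names(baseline_hazard)))
      stop("baseline_hazard must name the same outcomes as true_log_hr (death aside)",
           call. = FALSE)
    if (any(baseline_hazard < 0) || death_hazard < 0)
      stop("hazard rates must be >= 0", call. = FALSE)
    if (history_days <= 0)
      stop("history_days must be positive", call. = FALSE)
    if (missing_rate < 0 || missing_rate >= 1)
      stop("missing_rate must lie in [0, 1)", call. = FALSE)
    if (vaccination_rate < 0 || vaccination_rate > 1)
      stop("vaccination_rate must lie in [0, 1]", call. = FALSE)
    if (!is.null(care_setting_log_hr)) {
      bad <- vapply(care_setting_log_hr, function(v) length(v) != 3L, logical(1))
      if (any(bad) || !all(names(care_setting_log_hr) %in% outs))
        stop("care_setting_log_hr entries must be length-3 vectors named by outcome",
             call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Simulated outcome names of a configuration
#' @param config a `pa_sim_config`.
#' @return character vector of outcome names (death excluded).
#' @export
sim_outcomes <- function(config) setdiff(names(config$true_log_hr), "death")

# Draw n confounder vectors from the conditional law X | Z = z under the
# logistic selection model P(Z = 1 | x) = plogis(x %*% gamma), by rejection.
draw_confounders <- function(n, m, gamma, exposed) {
  if (m == 0L) return(matrix(numeric(0), nrow = n, ncol = 0))
  out <- matrix(NA_real_, n, m)
  filled <- 0L
  while (filled < n) {
    k <- max(2L * (n - filled), 100L)
    prop <- matrix(stats::rnorm(k * m), ncol = m)
    p <- stats::plogis(drop(prop %*% gamma))
    keep <- stats::runif(k) < (if (exposed) p else 1 - p)
    nk <- min(sum(keep), n - filled)
    if (nk > 0L) {
      out[(filled + 1L):(filled + nk), ] <- prop[which(keep)[seq_len(nk)], , drop = FALSE]
      filled <- filled + nk
    }
  }
  out
}

# Exponential draw that tolerates rate 0 (never fires).
rexp_safe <- function(n, rate) {
  t <- rep(Inf, n)
  pos <- rate > 0
  if (any(pos)) t[pos] <- stats::rexp(sum(pos), rate[pos])
  t
}

#' Generate a seeded synthetic cohort
#'
#' Produces a `pa_cohort`: a persons table (group, care setting, T0 for the
#' exposed, death and vaccination dates, pre-defined covariates with MCAR
#' missingness, confounders), a long events table of first outcome
#' occurrences, and a long codes table of sparse (domain, code, date)
#' occurrences. Control persons carry no T0; assign one with
#' [assign_t0()]. See [sim_config()] for the data-generating model.
#'
#' @param config a [sim_config()] object.
#' @return object of class `pa_cohort`: list with elements `persons`,
#'   `events`, `codes`, `config`.
#' @examples
#' coh <- generate_cohort(sim_config(n_exposed = 200, n_contemporary = 300,
#'                                   n_historical = 0, seed = 7,
#'                                   n_noise_codes_per_domain = c(20, 20, 5)))
#' table(coh$persons$group)
#' @export
generate_cohort <- function(config) {
  validate_sim_config(unclass(config))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n_e <- config$n_exposed; n_c <- config$n_contemporary; n_h <- config$n_historical
  n <- n_e + n_c + n_h
  m <- config$n_confounders
  gam <- config$confounder_effect_on_exposure
  off <- config$historical_offset_days

  group <- factor(rep(c("exposed", "contemporary", "historical"),
                      c(n_e, n_c, n_h)),
                  levels = c("exposed", "contemporary", "historical"))
  X <- rbind(draw_confounders(n_e, m, gam, exposed = TRUE),
             draw_confounders(n_c, m, gam, exposed = FALSE),
             draw_confounders(n_h, m, gam, exposed = FALSE))
  if (m > 0L) colnames(X) <- paste0("x", seq_len(m))

  probs <- config$enrollment_probs
  t0 <- rep(as.Date(NA), n)
  t0[group == "exposed"] <- if (is.null(probs))
    sample(config$enrollment_dates, n_e, replace = TRUE)
  else
    sample(config$enrollment_dates, n_e, replace = TRUE, prob = probs)

  care_setting <- factor(rep("none", n),
                         levels = c("none", "non_hospitalized", "hospitalized", "icu"))
  care_setting[group == "exposed"] <-
    sample(c("non_hospitalized", "hospitalized", "icu"), n_e, replace = TRUE,
           prob = config$care_setting_probs)

  # calendar origin of each person's event clock
  win_start <- min(config$enrollment_dates)
  origin <- rep(win_start - config$history_days, n)
  hist_rows <- group == "historical"
  origin[hist_rows] <- origin[hist_rows] - off
  cal_end <- rep(config$admin_censor_date, n)
  cal_end[hist_rows] <- cal_end[hist_rows] - off

  eta <- if (m > 0L) drop(X %*% config$confounder_effect_on_hazard) else rep(0, n)
  exposed_rows <- group == "exposed"
  cs_idx <- as.integer(factor(care_setting[exposed_rows],
                              levels = c("non_hospitalized", "hospitalized", "icu")))

  # exposure log HR per exposed person for a given cause
  exposed_beta <- function(outcome) {
    cs <- config$care_setting_log_hr
    if (!is.null(cs) && outcome %in% names(cs)) cs[[outcome]][cs_idx]
    else rep(unname(config$true_log_hr[outcome]), sum(exposed_rows))
  }

  # two-phase competing-exponential draw: unexposed rate before T0,
  # exposure-multiplied rate after (memoryless restart at T0)
  draw_cause <- function(base_rate, beta_name) {
    rate0 <- base_rate * exp(eta)
    date <- origin + rexp_safe(n, rate0)
    if (any(exposed_rows)) {
      e <- which(exposed_rows)
      late <- e[date[e] >= t0[e]]            # survived unexposed phase to T0
      if (length(late)) {
        beta_all <- if (beta_name %in% names(config$true_log_hr) ||
                        (!is.null(config$care_setting_log_hr) &&
                         beta_name %in% names(config$care_setting_log_hr)))
          exposed_beta(beta_name) else rep(0, sum(exposed_rows))
        beta <- beta_all[match(late, e)]
        date[late] <- t0[late] + rexp_safe(length(late), rate0[late] * exp(beta))
      }
    }
    date
  }

  floor_date <- function(d) as.Date(floor(unclass(d)), origin = "1970-01-01")

  death_beta <- if ("death" %in% names(config$true_log_hr)) "death" else "none"
  death_date <- draw_cause(config$death_hazard, death_beta)

  outcomes <- sim_outcomes(config)
  ev_list <- vector("list", length(outcomes))
  for (j in seq_along(outcomes)) {
    dj <- draw_cause(config$baseline_hazard[outcomes[j]], outcomes[j])
    obs <- dj < death_date & dj <= cal_end
    ev_list[[j]] <- data.frame(person_id = which(obs),
                               outcome = rep(outcomes[j], sum(obs)),
                               date = floor_date(dj[obs]),
                               stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev_list)
  if (is.null(events))
    events <- data.frame(person_id = integer(0), outcome = character(0),
                         date = as.Date(character(0)))
  death_date <- floor_date(death_date)
  death_date[death_date > cal_end] <- NA

  # pre-defined clinical covariates (noise relative to the configured
  # confounders; carry the realistic scales the design matrix expects)
  persons <- data.frame(
    person_id = seq_len(n),
    group = group,
    care_setting = care_setting,
    t0 = t0,
    death_date = death_date,
    age = round(pmin(pmax(stats::rnorm(n, 62, 12), 20), 95), 1),
    sex = factor(sample(c("male", "female"), n, TRUE, prob = c(0.9, 0.1))),
    race = factor(sample(c("White", "Black", "Other"), n, TRUE,
                         prob = c(0.75, 0.18, 0.07))),
    adi = round(pmin(pmax(stats::rnorm(n, 50, 20), 1), 100), 1),
    bmi = round(stats::rnorm(n, 29, 5), 1),
    smoking = factor(sample(c("never", "former", "current"), n, TRUE,
                            prob = c(0.45, 0.35, 0.20))),
    outpatient_count = stats::rpois(n, 5),
    inpatient_count = stats::rpois(n, 0.3),
    long_term_care = stats::rbinom(n, 1, 0.03),
    cancer = stats::rbinom(n, 1, 0.08),
    ckd = stats::rbinom(n, 1, 0.10),
    chronic_lung_disease = stats::rbinom(n, 1, 0.12),
    dementia = stats::rbinom(n, 1, 0.04),
    diabetes = stats::rbinom(n, 1, 0.25),
    dysautonomia = stats::rbinom(n, 1, 0.01),
    hyperlipidemia = stats::rbinom(n, 1, 0.45),
    hypertension = stats::rbinom(n, 1, 0.55),
    egfr = round(pmin(pmax(stats::rnorm(n, 75, 18), 5), 130), 1),
    sbp = round(stats::rnorm(n, 132, 16), 0),
    dbp = round(stats::rnorm(n, 78, 10), 0),
    stringsAsFactors = FALSE)
  if (m > 0L) persons <- cbind(persons, as.data.frame(X))

  # MCAR missingness on the continuous clinical measurements
  if (config$missing_rate > 0) {
    for (v in c("adi", "bmi", "egfr", "sbp", "dbp")) {
      miss <- stats::runif(n) < config$missing_rate
      persons[[v]][miss] <- NA
    }
  }

  vac <- rep(as.Date(NA), n)
  vac_window_start <- as.Date("2020-12-11")  # first vaccine availability
  elig <- !hist_rows & stats::runif(n) < config$vaccination_rate
  n_v <- sum(elig)
  if (n_v > 0) {
    span <- as.numeric(config$admin_censor_date - vac_window_start)
    vac[elig] <- vac_window_start + floor(stats::runif(n_v) * (span + 1))
  }
  persons$vaccination_date <- vac

  codes <- simulate_codes(n, X, origin, cal_end, config)

  structure(list(persons = persons, events = events, codes = codes,
                 config = config),
            class = "pa_cohort",
            data_start = min(origin))
}

# Sparse code occurrences: per-domain noise codes at constant prevalence,
# plus a few "signal" codes whose prevalence rides on the confounders.
simulate_codes <- function(n, X, origin, cal_end, config) {
  domains <- c("diagnosis", "medication", "laboratory")
  eta_code <- if (ncol(X) > 0L)
    drop(X %*% rep(0.8, ncol(X))) else rep(0, n)
  span <- as.numeric(cal_end - origin)
  pieces <- list()
  for (d in seq_along(domains)) {
    n_codes <- config$n_noise_codes_per_domain[d]
    if (n_codes == 0L) next
    n_sig <- min(config$n_signal_codes_per_domain[d], n_codes)
    base_logit <- stats::runif(n_codes, -6.5, -3.5)
    ids <- sprintf("%s_%04d", toupper(substr(domains[d], 1, 3)), seq_len(n_codes))
    for (k in seq_len(n_codes)) {
      p <- if (k <= n_sig) stats::plogis(base_logit[k] + eta_code)
           else rep(stats::plogis(base_logit[k]), n)
      hit <- which(stats::runif(n) < p)
      if (length(hit))
        pieces[[length(pieces) + 1L]] <-
          data.frame(person_id = hit, domain = domains[d], code = ids[k],
                     date = origin[hit] + floor(stats::runif(length(hit)) *
                                                (span[hit] + 1)),
                     stringsAsFactors = FALSE)
    }
  }
  if (length(pieces)) do.call(rbind, pieces)
  else data.frame(person_id = integer(0), domain = character(0),
                  code = character(0), date = as.Date(character(0)))
}

#' Inject pre-index outcome history into a cohort
#'
#' Gives a seeded, exactly-sized fraction of persons an occurrence of
#' `outcome` inside the year before their T0, to exercise the
#' history-exclusion rule of [build_subcohort()]. Only persons with a
#' non-missing T0 participate (the pre-T0 window is undefined otherwise),
#' so run [assign_t0()] first if controls should be eligible.
#'
#' @param cohort a `pa_cohort`.
#' @param outcome one of `sim_outcomes(cohort$config)`.
#' @param fraction fraction in \[0, 1\]; exactly `round(fraction * n)`
#'   persons (n = persons with T0) are flagged.
#' @param seed integer seed for the draw.
#' @return the modified `pa_cohort`.
#' @export
inject_history <- function(cohort, outcome, fraction, seed = 1L) {
  stopifnot(inherits(cohort, "pa_cohort"))
  if (!outcome %in% sim_outcomes(cohort$config))
    stop("unknown outcome: ", outcome, call. = FALSE)
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  eligible <- which(!is.na(cohort$persons$t0))
  n_flag <- round(fraction * length(eligible))
  if (n_flag == 0L) return(cohort)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  chosen <- sample(eligible, n_flag)
  t0 <- cohort$persons$t0[chosen]
  hist_date <- t0 - 1L - floor(stats::runif(n_flag) * 364)  # in [T0-365, T0-1]
  ev <- cohort$events
  # replace any existing first occurrence: history date precedes it
  drop_rows <- ev$outcome == outcome & ev$person_id %in% chosen
  ev <- ev[!drop_rows, , drop = FALSE]
  ev <- rbind(ev, data.frame(person_id = chosen, outcome = outcome,
                             date = hist_date, stringsAsFactors = FALSE))
  cohort$events <- ev[order(ev$outcome, ev$person_id), , drop = FALSE]
  rownames(cohort$events) <- NULL
  cohort
}

#' @export
print.pa_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$persons), "persons\n")
  print(table(x$persons$group))
  cat(nrow(x$events), "outcome events across",
      length(sim_outcomes(x$config)), "outcomes;",
      nrow(x$codes), "code occurrences\n")
  invisible(x)
}

#' Write a cohort to delimited text files
#'
#' Writes `persons.tsv`, `events.tsv` and `codes.tsv` (tab-delimited) plus
#' `config.yaml` into `dir`.
#'
#' @param cohort a `pa_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pa_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wr(cohort$persons, "persons.tsv")
  wr(cohort$events, "events.tsv")
  wr(cohort$codes, "codes.tsv")
  cfg <- unclass(cohort$config)
  cfg$enrollment_dates <- as.character(cfg$enrollment_dates)
  cfg$admin_censor_date <- as.character(cfg$admin_censor_date)
  cfg$true_log_hr <- as.list(cfg$true_log_hr)       # yaml drops vector names
  cfg$baseline_hazard <- as.list(cfg$baseline_hazard)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory holding `persons.tsv`, `events.tsv`, `codes.tsv`,
#'   `config.yaml`.
#' @return a `pa_cohort`.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE, stringsAsFactors = FALSE)
  persons <- rd("persons.tsv")
  for (v in c("t0", "death_date", "vaccination_date"))
    persons[[v]] <- as.Date(persons[[v]])
  for (v in c("group", "care_setting", "sex", "race", "smoking"))
    persons[[v]] <- factor(persons[[v]])
  persons$group <- factor(persons$group,
                          levels = c("exposed", "contemporary", "historical"))
  persons$care_setting <- factor(persons$care_setting,
                                 levels = c("none", "non_hospitalized",
                                            "hospitalized", "icu"))
  events <- rd("events.tsv"); events$date <- as.Date(events$date)
  codes <- rd("codes.tsv"); codes$date <- as.Date(codes$date)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$enrollment_dates <- as.Date(cfg$enrollment_dates)
  cfg$admin_censor_date <- as.Date(cfg$admin_censor_date)
  cfg$true_log_hr <- unlist(cfg$true_log_hr)
  cfg$baseline_hazard <- unlist(cfg$baseline_hazard)
  cfg <- do.call(sim_config, cfg[names(cfg) %in% names(formals(sim_config))])
  structure(list(persons = persons, events = events, codes = codes,
                 config = cfg),
            class = "pa_cohort",
            data_start = cohort_data_start_from_config(cfg))
}

# earliest calendar date any event clock could produce
cohort_data_start_from_config <- function(cfg) {
  start <- min(cfg$enrollment_dates) - cfg$history_days
  if (cfg$n_historical > 0L) start <- start - cfg$historical_offset_days
  start
}
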