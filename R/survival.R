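subcohort_frame <- function(subcohort, exposed_level = "exposed") {
  data.frame(person_id = subcohort$person_id,
             time = subcohort$time,
             event = subcohort$event,
             death = subcohort$death,
             exposed = as.numeric(subcohort$group == exposed_level))
}

make_hazard_result <- function(log_hr, se, outcome, comparison, n_exposed,
                               n_control, events, model = NULL, extra = NULL) {
  hr <- exp(log_hr)
  ci <- exp(log_hr + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(c(list(outcome = outcome, comparison = comparison,
                   hr = hr, log_hr = log_hr, log_hr_se = se,
                   ci95 = ci, n_exposed = n_exposed, n_control = n_control,
                   events = events,
                   significant = ci[1] > 1 || ci[2] < 1,
                   model = model),
              extra),
            class = "pa_hazard")
}

#' @export
print.pa_hazard <- function(x, ...) {
  cat(sprintf("%s (%s): HR %.3f (95%% CI %.3f-%.3f)%s\n",
              x$outcome, x$comparison, x$hr, x$ci95[1], x$ci95[2],
              if (x$significant) " *" else ""))
  cat(sprintf("  n exposed %d, n control %d, events %d\n",
              x$n_exposed, x$n_control, x$events))
  if (isTRUE(x$aliased))
    cat("  note: time-varying term aliased with a baseline covariate\n")
  invisible(x)
}

#' Weighted cause-specific Cox model
#'
#' Fits the group hazard ratio by weighted Cox partial likelihood (Efron
#' tie handling), treating deaths as censoring of the outcome of interest
#' (cause-specific hazard with death as a competing risk) — the `death`
#' indicator of the subcohort rows never enters as an event. Variance is
#' the robust sandwich estimator with persons as independent clusters,
#' which accounts for the weights being estimated. For the doubly robust
#' variant, pass the covariate `design_matrix` to adjust in the outcome
#' model as well.
#'
#' @param subcohort a `pa_subcohort` restricted to one comparison (the
#'   exposed group plus one control group).
#' @param weights per-row nonnegative weights.
#' @param design_matrix optional covariate matrix (doubly robust runs).
#' @param exposed_level group level treated as exposed (default
#'   `"exposed"`).
#' @param comparison label stored in the result.
#' @return object of class `pa_hazard`: hazard ratio, robust SE of the
#'   log HR, 95\% CI, counts, and significance per the rule that the CI
#'   excludes unity.
#' @export
fit_weighted_cox <- function(subcohort, weights = NULL, design_matrix = NULL,
                             exposed_level = "exposed",
                             comparison = "contemporary") {
  dat <- subcohort_frame(subcohort, exposed_level)
  if (is.null(weights)) weights <- rep(1, nrow(dat))
  for (side in c(0, 1))
    if (sum(dat$event[dat$exposed == side]) == 0L)
      stop("no events in the ",
           if (side == 1) "exposed" else "control", " group", call. = FALSE)
  dat$.w <- weights
  rhs <- "exposed"
  if (!is.null(design_matrix)) {
    dm <- as.data.frame(design_matrix)
    names(dm) <- make.names(names(dm), unique = TRUE)
    dat <- cbind(dat, dm)
    rhs <- c(rhs, names(dm))
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, weights = dat$.w, robust = TRUE,
                         ties = "efron")
  make_hazard_result(log_hr = unname(stats::coef(fit)["exposed"]),
                     se = sqrt(fit$var[1L, 1L]),
                     outcome = attr(subcohort, "outcome"),
                     comparison = comparison,
                     n_exposed = sum(dat$exposed == 1),
                     n_control = sum(dat$exposed == 0),
                     events = sum(dat$event),
                     model = fit)
}

#' Weighted cumulative incidence (Aalen-Johansen) at a horizon
#'
#' Weighted Aalen-Johansen estimate of the cumulative incidence of the
#' outcome at `horizon_days`, with death as a competing event, per group,
#' scaled to events per 1,000 persons (the 12-month "burden" when the
#' horizon is 365 d). With no competing deaths present it reduces exactly
#' to 1 minus the Kaplan-Meier estimator.
#'
#' @param subcohort a `pa_subcohort`.
#' @param weights per-row weights (unit when `NULL`).
#' @param horizon_days evaluation time in days from the entry origin; must
#'   not exceed the longest follow-up of any group present.
#' @return object of class `pa_cif`: data frame with `group`, `burden`
#'   (per 1,000), `n`, `events`.
#' @export
estimate_cif <- function(subcohort, weights = NULL, horizon_days = 365) {
  if (is.null(weights)) weights <- rep(1, nrow(subcohort))
  groups <- levels(droplevels(subcohort$group))
  res <- data.frame(group = groups, burden = NA_real_,
                    n = NA_integer_, events = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    rows <- subcohort$group == groups[i]
    if (max(subcohort$time[rows]) < horizon_days)
      stop("horizon ", horizon_days, " d exceeds all follow-up in group ",
           groups[i], call. = FALSE)
    res$burden[i] <- 1000 * aj_event_probability(
      subcohort$time[rows], subcohort$event[rows], subcohort$death[rows],
      weights[rows], horizon_days)
    res$n[i] <- sum(rows)
    res$events[i] <- sum(subcohort$event[rows])
  }
  class(res) <- c("pa_cif", "data.frame")
  res
}

# weighted AJ P(event by horizon) via survfit multi-state
aj_event_probability <- function(time, event, death, w, horizon) {
  state <- factor(ifelse(event == 1, "event",
                         ifelse(death == 1, "death", "censor")),
                  levels = c("censor", "event", "death"))
  dat <- data.frame(time = time, state = state, w = w)
  fit <- survival::survfit(survival::Surv(time, state) ~ 1, data = dat,
                           weights = dat$w)
  s <- summary(fit, times = horizon, extend = TRUE)
  unname(s$pstate[1L, match("event", fit$states)])
}

#' @export
print.pa_cif <- function(x, ...) {
  cat("Cumulative incidence per 1,000 persons\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Excess burden per 1,000 persons with bootstrap confidence intervals
#'
#' Point estimates come from the weighted Aalen-Johansen burdens of
#' [estimate_cif()]; the excess burden is exactly their difference.
#' Confidence intervals are percentile intervals from a nonparametric
#' bootstrap over persons (resampled within group, weights travelling
#' with their persons).
#'
#' @param subcohort a `pa_subcohort` containing the exposed group and one
#'   control group.
#' @param weights per-row weights.
#' @param horizon_days burden horizon (default 365).
#' @param resamples bootstrap replicates (default 500; must be >= 2).
#' @param seed integer seed.
#' @param exposed_level group level treated as exposed.
#' @return object of class `pa_burden`: list with `burden_exposed`,
#'   `burden_control`, `excess_burden`, each with a `ci95`, and the
#'   horizon and resample count.
#' @export
excess_burden <- function(subcohort, weights = NULL, horizon_days = 365,
                          resamples = 500L, seed = 1L,
                          exposed_level = "exposed") {
  if (resamples < 2L) stop("resamples must be >= 2", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(subcohort))
  exp_rows <- which(subcohort$group == exposed_level)
  ctl_rows <- which(subcohort$group != exposed_level)
  point <- function(re, rc) {
    be <- 1000 * aj_event_probability(subcohort$time[re], subcohort$event[re],
                                      subcohort$death[re], weights[re],
                                      horizon_days)
    bc <- 1000 * aj_event_probability(subcohort$time[rc], subcohort$event[rc],
                                      subcohort$death[rc], weights[rc],
                                      horizon_days)
    c(be, bc, be - bc)
  }
  est <- point(exp_rows, ctl_rows)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  boot <- matrix(NA_real_, resamples, 3L)
  for (b in seq_len(resamples)) {
    re <- sample(exp_rows, length(exp_rows), replace = TRUE)
    rc <- sample(ctl_rows, length(ctl_rows), replace = TRUE)
    boot[b, ] <- point(re, rc)
  }
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(outcome = attr(subcohort, "outcome"),
                 burden_exposed = est[1L], burden_exposed_ci95 = ci[, 1L],
                 burden_control = est[2L], burden_control_ci95 = ci[, 2L],
                 excess_burden = est[3L], excess_burden_ci95 = ci[, 3L],
                 horizon_days = horizon_days, resamples = resamples),
            class = "pa_burden")
}

#' @export
print.pa_burden <- function(x, ...) {
  cat(sprintf("Burden per 1,000 at %d d (%s)\n", x$horizon_days,
              if (is.null(x$outcome)) "outcome" else x$outcome))
  cat(sprintf("  exposed  %.2f (%.2f-%.2f)\n", x$burden_exposed,
              x$burden_exposed_ci95[1], x$burden_exposed_ci95[2]))
  cat(sprintf("  control  %.2f (%.2f-%.2f)\n", x$burden_control,
              x$burden_control_ci95[1], x$burden_control_ci95[2]))
  cat(sprintf("  excess   %.2f (%.2f-%.2f)\n", x$excess_burden,
              x$excess_burden_ci95[1], x$excess_burden_ci95[2]))
  invisible(x)
}

#' Censor a subcohort at per-person event dates
#'
#' Truncates follow-up at an external censoring event (e.g., first
#' vaccine dose): exit becomes the earlier of the current exit and the
#' censoring date, outcomes and competing deaths after it are wiped.
#' Persons whose censoring date falls on or before entry are dropped;
#' their count is reported via a warning and the `dropped` attribute.
#'
#' @param subcohort a `pa_subcohort`.
#' @param event_dates `Date` vector named by `person_id` (persons absent
#'   from it are untouched; `NA` entries likewise).
#' @return the censored `pa_subcohort`.
#' @export
censor_at <- function(subcohort, event_dates) {
  if (length(event_dates) == 0L) return(subcohort)
  idx <- match(as.character(subcohort$person_id), names(event_dates))
  cd <- as.Date(unname(event_dates[idx]))
  ct <- as.numeric(cd - subcohort$entry_date)
  drop <- !is.na(ct) & ct <= 0
  trunc <- !is.na(ct) & !drop & ct < subcohort$time
  subcohort$time[trunc] <- ct[trunc]
  subcohort$event[trunc] <- 0L
  subcohort$death[trunc] <- 0L
  if (any(drop))
    warning(sum(drop), " person(s) dropped: censoring date on or before entry",
            call. = FALSE)
  out <- subcohort[!drop, , drop = FALSE]
  attr(out, "outcome") <- attr(subcohort, "outcome")
  attr(out, "dropped") <- sum(drop)
  out
}

#' Cox model with a time-varying 0/1 covariate
#'
#' Episode-splits each person at the switch date (e.g., first vaccine
#' dose) and fits the weighted cause-specific Cox model with the group
#' term plus the time-varying indicator. A switch on or before entry
#' makes the indicator 1 throughout; a switch after exit never fires.
#' If the indicator is aliased with a baseline covariate (e.g., everyone
#' switched at entry) the result carries `aliased = TRUE`.
#'
#' @param subcohort a `pa_subcohort`.
#' @param weights per-row weights.
#' @param tv_covariate_dates `Date` vector named by `person_id`.
#' @param exposed_level,comparison as in [fit_weighted_cox()].
#' @return a `pa_hazard` with extra fields `tv_coef` and `aliased`.
#' @export
fit_time_varying <- function(subcohort, weights = NULL, tv_covariate_dates,
                             exposed_level = "exposed",
                             comparison = "contemporary") {
  dat <- subcohort_frame(subcohort, exposed_level)
  if (is.null(weights)) weights <- rep(1, nrow(dat))
  dat$.w <- weights
  idx <- match(as.character(dat$person_id), names(tv_covariate_dates))
  s <- as.numeric(as.Date(unname(tv_covariate_dates[idx])) -
                  subcohort$entry_date)
  pre <- is.na(s) | s >= dat$time        # never switches during follow-up
  from_start <- !is.na(s) & s <= 0       # switched at or before entry
  split <- !pre & !from_start

  one <- dat[!split, , drop = FALSE]
  one$tstart <- 0; one$tstop <- one$time
  one$tv <- as.numeric(from_start[!split])
  pieces <- list(one)
  if (any(split)) {
    a <- dat[split, , drop = FALSE]
    a$tstart <- 0; a$tstop <- s[split]; a$tv <- 0; a$event <- 0L
    b <- dat[split, , drop = FALSE]
    b$tstart <- s[split]; b$tstop <- b$time; b$tv <- 1
    pieces <- c(pieces, list(a, b))
  }
  long <- do.call(rbind, pieces)
  # a never-varying indicator is expected in degenerate inputs; coxph then
  # warns about singularity while we report the aliasing explicitly
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(tstart, tstop, event) ~ exposed + tv,
      data = long, weights = long$.w, robust = TRUE, ties = "efron",
      id = long$person_id),
    warning = function(w) {
      if (grepl("singular|beta may be infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  make_hazard_result(log_hr = unname(cf["exposed"]),
                     se = sqrt(fit$var[1L, 1L]),
                     outcome = attr(subcohort, "outcome"),
                     comparison = comparison,
                     n_exposed = sum(dat$exposed == 1),
                     n_control = sum(dat$exposed == 0),
                     events = sum(dat$event),
                     model = fit,
                     extra = list(tv_coef = unname(cf["tv"]),
                                  aliased = is.na(cf["tv"])))
}
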