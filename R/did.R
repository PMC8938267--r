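#' Build the matched pre-exposure period table
#'
#' For each landmark survivor the pre-exposure window has exactly the same
#' per-person length as their post-exposure follow-up and ends at T0.
#' Persons with an occurrence of the outcome in the year before the
#' pre-period start are excluded (incident-rate logic mirrors the
#' post-period subcohort), and persons whose lookback-extended window
#' would reach before the start of available data are dropped with a
#' reported count.
#'
#' @param cohort a landmark-filtered `pa_cohort`.
#' @param outcome outcome (or composite) name.
#' @param spec the [cohort_spec()].
#' @param composites composite definitions (see [default_composites()]).
#' @return object of class `pa_period`: data frame with `person_id`,
#'   `group`, `care_setting`, `events` (0/1 first occurrence inside the
#'   window), `persontime` (days at risk, truncated at the first
#'   occurrence), plus attribute `dropped_insufficient_history`.
#' @export
build_pre_period <- function(cohort, outcome, spec = cohort_spec(),
                             composites = default_composites()) {
  p <- cohort$persons
  if (is.null(p$entry_date))
    stop("apply_landmark() must run before build_pre_period()", call. = FALSE)
  components <- if (outcome %in% names(composites)) composites[[outcome]]
                else outcome
  ev_components <- setdiff(components, "death")
  death_is_event <- "death" %in% components

  eof <- group_end_of_followup(spec, p$group)
  post_exit <- pmin(eof, p$death_date, na.rm = TRUE)
  post_fu <- as.numeric(post_exit - p$entry_date)   # per-person post length
  pre_start <- p$t0 - post_fu

  data_start <- attr(cohort, "data_start")
  insufficient <- if (!is.null(data_start))
    (pre_start - spec$lookback_days) < data_start else rep(FALSE, nrow(p))

  ev <- cohort$events[cohort$events$outcome %in% ev_components, , drop = FALSE]
  first_ev <- rep(as.Date(NA), nrow(p))
  if (nrow(ev)) {
    agg <- tapply(as.numeric(ev$date), as.character(ev$person_id), min)
    idx <- match(names(agg), as.character(p$person_id))
    ok <- !is.na(idx)
    first_ev[idx[ok]] <- as.Date(unname(agg[ok]), origin = "1970-01-01")
  }
  # death cannot occur before T0 for landmark survivors, so a "death"
  # component contributes nothing to the pre-period

  history <- !is.na(first_ev) &
    first_ev >= (pre_start - spec$lookback_days) & first_ev < pre_start
  keep <- !history & !insufficient & post_fu > 0

  q <- p[keep, , drop = FALSE]
  fe <- first_ev[keep]; ps <- pre_start[keep]
  in_window <- !is.na(fe) & fe >= ps & fe < q$t0
  pt <- as.numeric(q$t0 - ps)
  pt[in_window] <- as.numeric(fe[in_window] - ps[in_window])
  events <- as.integer(in_window)
  pos <- pt > 0
  out <- data.frame(person_id = q$person_id[pos],
                    group = droplevels(q$group[pos]),
                    care_setting = q$care_setting[pos],
                    events = events[pos],
                    persontime = pt[pos],
                    stringsAsFactors = FALSE)
  structure(out, class = c("pa_period", "data.frame"),
            outcome = outcome, period = "pre",
            dropped_insufficient_history = sum(insufficient),
            excluded_history = sum(history))
}

#' Convert a post-period subcohort to a period table
#'
#' @param subcohort a `pa_subcohort` from [build_subcohort()].
#' @return a `pa_period` with events and person-time from the subcohort's
#'   follow-up (death and administrative censoring already applied).
#' @export
as_period <- function(subcohort) {
  out <- data.frame(person_id = subcohort$person_id,
                    group = subcohort$group,
                    care_setting = subcohort$care_setting,
                    events = subcohort$event,
                    persontime = subcohort$time,
                    stringsAsFactors = FALSE)
  structure(out, class = c("pa_period", "data.frame"),
            outcome = attr(subcohort, "outcome"), period = "post")
}

# weighted rate and sandwich variance of its log
weighted_rate <- function(events, persontime, w) {
  sw_e <- sum(w * events); sw_t <- sum(w * persontime)
  if (sw_e == 0) stop("zero events", call. = FALSE)
  lambda <- sw_e / sw_t
  # influence-function variance of log(lambda), persons independent
  infl <- w * (events - lambda * persontime) / sw_t
  list(rate = lambda, var_log = sum(infl^2) / lambda^2)
}

#' Weighted incident rate ratio
#'
#' `IRR = (sum w e / sum w t)_exposed / (sum w e / sum w t)_control`, with
#' a person-level sandwich (influence-function) variance on the log scale.
#'
#' @param period a `pa_period` (or any data frame with `events`,
#'   `persontime`, `group`).
#' @param weights per-row weights (unit when `NULL`).
#' @param exposed_level group level forming the numerator.
#' @return object of class `pa_irr`: list with `irr`, `log_irr`, `se`,
#'   `ci95`, per-group rates and totals.
#' @export
incident_rate_ratio <- function(period, weights = NULL,
                                exposed_level = "exposed") {
  if (is.null(weights)) weights <- rep(1, nrow(period))
  i1 <- period$group == exposed_level
  if (!any(i1) || !all(c(TRUE, FALSE) %in% unique(i1)))
    stop("period must contain the exposed level and one control group",
         call. = FALSE)
  if (sum(period$events[!i1]) == 0)
    stop("zero events in the control (denominator) group", call. = FALSE)
  if (sum(period$events[i1]) == 0)
    stop("zero events in the exposed group", call. = FALSE)
  r1 <- weighted_rate(period$events[i1], period$persontime[i1], weights[i1])
  r0 <- weighted_rate(period$events[!i1], period$persontime[!i1], weights[!i1])
  log_irr <- log(r1$rate / r0$rate)
  se <- sqrt(r1$var_log + r0$var_log)
  structure(list(irr = exp(log_irr), log_irr = log_irr, se = se,
                 ci95 = exp(log_irr + c(-1, 1) * stats::qnorm(0.975) * se),
                 rate_exposed = r1$rate, rate_control = r0$rate,
                 events = sum(period$events),
                 outcome = attr(period, "outcome"),
                 period = attr(period, "period")),
            class = "pa_irr")
}

#' @export
print.pa_irr <- function(x, ...) {
  cat(sprintf("IRR%s: %.3f (95%% CI %.3f-%.3f), %d events\n",
              if (is.null(x$period)) "" else paste0(" [", x$period, "]"),
              x$irr, x$ci95[1], x$ci95[2], x$events))
  invisible(x)
}

#' Ratio of post- to pre-exposure incident rate ratios
#'
#' The difference-in-differences estimand on the ratio scale:
#' `ratio = IRR_post / IRR_pre`. The default CI treats the two periods as
#' independent (log-scale variance addition); since the same persons
#' contribute to both periods this understates their correlation, so
#' [did_estimate()] offers a joint person-level bootstrap.
#'
#' @param irr_pre,irr_post `pa_irr` objects.
#' @return object of class `pa_did`.
#' @export
did_ratio <- function(irr_pre, irr_post) {
  stopifnot(inherits(irr_pre, "pa_irr"), inherits(irr_post, "pa_irr"))
  if (irr_pre$irr <= 0 || irr_post$irr <= 0)
    stop("IRRs must be positive", call. = FALSE)
  lr <- irr_post$log_irr - irr_pre$log_irr
  se <- sqrt(irr_pre$se^2 + irr_post$se^2)
  structure(list(outcome = irr_post$outcome,
                 irr_pre = irr_pre$irr, irr_pre_ci95 = irr_pre$ci95,
                 irr_post = irr_post$irr, irr_post_ci95 = irr_post$ci95,
                 ratio_of_irr = exp(lr),
                 ci95 = exp(lr + c(-1, 1) * stats::qnorm(0.975) * se),
                 method = "independent-period variance"),
            class = "pa_did")
}

#' Difference-in-differences estimate with joint bootstrap CI
#'
#' Computes pre- and post-period weighted IRRs and their ratio, with a
#' percentile CI from a nonparametric bootstrap that resamples *persons*
#' and carries each person's pre- and post-period rows (and weights)
#' together, preserving the between-period correlation induced by person
#' overlap. Weights are held fixed across resamples.
#'
#' @param pre_period,post_period `pa_period` tables.
#' @param pre_weights,post_weights per-row weights aligned with the
#'   period tables.
#' @param resamples bootstrap replicates (default 500).
#' @param seed integer seed.
#' @param exposed_level numerator group level.
#' @return a `pa_did` whose `ci95` is the bootstrap percentile interval
#'   (point estimates from the full sample).
#' @export
did_estimate <- function(pre_period, post_period, pre_weights = NULL,
                         post_weights = NULL, resamples = 500L, seed = 1L,
                         exposed_level = "exposed") {
  if (resamples < 2L) stop("resamples must be >= 2", call. = FALSE)
  if (is.null(pre_weights)) pre_weights <- rep(1, nrow(pre_period))
  if (is.null(post_weights)) post_weights <- rep(1, nrow(post_period))
  irr_pre <- incident_rate_ratio(pre_period, pre_weights, exposed_level)
  irr_post <- incident_rate_ratio(post_period, post_weights, exposed_level)
  out <- did_ratio(irr_pre, irr_post)

  ids <- union(pre_period$person_id, post_period$person_id)
  pre_idx <- match(pre_period$person_id, ids)
  post_idx <- match(post_period$person_id, ids)
  grp <- character(length(ids))
  grp[pre_idx] <- as.character(pre_period$group)
  grp[post_idx] <- as.character(post_period$group)
  exp_ids <- which(grp == exposed_level)
  ctl_ids <- which(grp != exposed_level)

  # per-person aggregates, zero when absent from a period
  agg <- function(idx, val, n) { v <- numeric(n); v[idx] <- v[idx] + val; v }
  n_ids <- length(ids)
  pre_e <- agg(pre_idx, pre_weights * pre_period$events, n_ids)
  pre_t <- agg(pre_idx, pre_weights * pre_period$persontime, n_ids)
  post_e <- agg(post_idx, post_weights * post_period$events, n_ids)
  post_t <- agg(post_idx, post_weights * post_period$persontime, n_ids)

  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  ratios <- numeric(resamples)
  for (b in seq_len(resamples)) {
    se_ <- sample(exp_ids, length(exp_ids), replace = TRUE)
    sc <- sample(ctl_ids, length(ctl_ids), replace = TRUE)
    num_pre <- sum(pre_e[se_]) / sum(pre_t[se_])
    den_pre <- sum(pre_e[sc]) / sum(pre_t[sc])
    num_post <- sum(post_e[se_]) / sum(post_t[se_])
    den_post <- sum(post_e[sc]) / sum(post_t[sc])
    ratios[b] <- (num_post / den_post) / (num_pre / den_pre)
  }
  ratios <- ratios[is.finite(ratios) & ratios > 0]
  out$ci95 <- unname(stats::quantile(ratios, c(0.025, 0.975)))
  out$method <- sprintf("person-level bootstrap (%d resamples)", resamples)
  out
}

#' @export
print.pa_did <- function(x, ...) {
  cat(sprintf("Difference-in-differences (%s)\n",
              if (is.null(x$outcome)) "outcome" else x$outcome))
  cat(sprintf("  IRR pre  %.3f (%.3f-%.3f)\n", x$irr_pre,
              x$irr_pre_ci95[1], x$irr_pre_ci95[2]))
  cat(sprintf("  IRR post %.3f (%.3f-%.3f)\n", x$irr_post,
              x$irr_post_ci95[1], x$irr_post_ci95[2]))
  cat(sprintf("  ratio    %.3f (%.3f-%.3f)  [%s]\n", x$ratio_of_irr,
              x$ci95[1], x$ci95[2], x$method))
  invisible(x)
}
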