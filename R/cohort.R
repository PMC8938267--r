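#' Cohort construction parameters
#'
#' @param landmark_days persons must survive strictly beyond
#'   `T0 + landmark_days` to enter follow-up (default 30).
#' @param lookback_days history window before T0 used for incident-outcome
#'   exclusion and covariate ascertainment (default 365).
#' @param historical_offset_days calendar shift applied to historical
#'   control T0 assignment (default 730).
#' @param end_of_followup named `Date` vector with entries `exposed`,
#'   `contemporary`, `historical`: administrative end of follow-up per
#'   group.
#' @param acute_events handling of outcome occurrences inside
#'   `(T0, T0 + landmark_days]`: `"exclude"` drops the person from that
#'   outcome's subcohort (they are not incident-disease-free at the time
#'   origin); `"ignore"` retains them event-free.
#' @return object of class `pa_cohort_spec`.
#' @export
cohort_spec <- function(landmark_days = 30L,
                        lookback_days = 365L,
                        historical_offset_days = 730L,
                        end_of_followup = c(exposed = "2021-10-31",
                                            contemporary = "2021-10-31",
                                            historical = "2019-10-31"),
                        acute_events = c("exclude", "ignore")) {
  if (landmark_days <= 0 || lookback_days <= 0 || historical_offset_days <= 0)
    stop("all durations must be positive", call. = FALSE)
  eof <- as.Date(end_of_followup)
  names(eof) <- names(end_of_followup)
  if (!all(c("exposed", "contemporary", "historical") %in% names(eof)))
    stop("end_of_followup must name all three groups", call. = FALSE)
  structure(list(landmark_days = as.integer(landmark_days),
                 lookback_days = as.integer(lookback_days),
                 historical_offset_days = as.integer(historical_offset_days),
                 end_of_followup = eof,
                 acute_events = match.arg(acute_events)),
            class = "pa_cohort_spec")
}

#' Draw control index dates from the exposed T0 distribution
#'
#' Controls receive a T0 sampled i.i.d. (with replacement) from the
#' empirical distribution of the exposed index dates, so the proportion of
#' people enrolled on each date matches the exposed group in expectation;
#' the historical group's dates are then shifted back by `offset_days` of
#' exact calendar days.
#'
#' @param exposed_t0_dates non-empty `Date` vector.
#' @param control_ids identifiers of the control persons.
#' @param offset_days days subtracted from each sampled date (0 for the
#'   contemporary group, 730 for the historical group).
#' @param seed integer seed.
#' @return named `Date` vector, one entry per element of `control_ids`.
#' @export
assign_control_t0 <- function(exposed_t0_dates, control_ids, offset_days = 0L,
                              seed = 1L) {
  exposed_t0_dates <- as.Date(exposed_t0_dates)
  if (length(exposed_t0_dates) == 0L || all(is.na(exposed_t0_dates)))
    stop("exposed_t0_dates must be non-empty", call. = FALSE)
  if (length(control_ids) == 0L)
    stop("control_ids must be non-empty", call. = FALSE)
  exposed_t0_dates <- exposed_t0_dates[!is.na(exposed_t0_dates)]
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  t0 <- sample(exposed_t0_dates, length(control_ids), replace = TRUE) - offset_days
  names(t0) <- as.character(control_ids)
  t0
}

#' Assign T0 to all control persons of a cohort
#'
#' Convenience wrapper over [assign_control_t0()]: contemporary controls
#' draw from the exposed T0 distribution unshifted; historical controls
#' draw from the same distribution shifted back by
#' `spec$historical_offset_days`.
#'
#' @param cohort a `pa_cohort`.
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return the cohort with `persons$t0` filled for every person.
#' @export
assign_t0 <- function(cohort, spec = cohort_spec(), seed = 1L) {
  p <- cohort$persons
  exp_t0 <- p$t0[p$group == "exposed"]
  for (g in c("contemporary", "historical")) {
    rows <- which(p$group == g & is.na(p$t0))
    if (length(rows) == 0L) next
    offs <- if (g == "historical") spec$historical_offset_days else 0L
    p$t0[rows] <- assign_control_t0(exp_t0, p$person_id[rows], offs,
                                    seed = seed + (g == "historical"))
  }
  cohort$persons <- p
  cohort
}

group_end_of_followup <- function(spec, group) {
  unname(spec$end_of_followup[as.character(group)])
}

#' Apply the landmark survival filter
#'
#' Restricts the cohort to persons alive strictly beyond
#' `T0 + landmark_days` whose follow-up window is non-degenerate, and
#' records the follow-up time origin `entry_date = T0 + landmark_days` for
#' the survivors. Death at exactly day `landmark_days` counts as
#' non-survival (survival *through* the landmark is required).
#'
#' @param cohort a `pa_cohort` with T0 assigned for every person.
#' @param spec a [cohort_spec()].
#' @return the cohort restricted to landmark survivors, with an
#'   `entry_date` column added and exclusion counts in
#'   `attr(, "exclusions")`.
#' @export
apply_landmark <- function(cohort, spec = cohort_spec()) {
  p <- cohort$persons
  if (anyNA(p$t0))
    stop("all persons must have T0 before the landmark filter; run assign_t0()",
         call. = FALSE)
  entry <- p$t0 + spec$landmark_days
  eof <- group_end_of_followup(spec, p$group)
  died_early <- !is.na(p$death_date) & p$death_date <= entry
  censored_early <- entry >= eof
  keep <- !died_early & !censored_early
  p <- p[keep, , drop = FALSE]
  p$entry_date <- entry[keep]
  cohort$persons <- p
  attr(cohort, "exclusions") <- c(died_before_landmark = sum(died_early),
                                  no_followup = sum(censored_early & !died_early))
  cohort
}

# composite outcome dictionary used when `outcome` names a composite;
# "death" as a component means all-cause mortality counts as an event
#' Composite outcome definitions
#'
#' Named list mapping composite names to component outcome names. `"mace"`
#' (all-cause mortality, myocardial infarction, stroke) treats death as an
#' event rather than a competing risk. Pass entries of this form to the
#' `composites` argument of [build_subcohort()].
#' @return named list of character vectors.
#' @export
default_composites <- function() {
  list(mace = c("death", "myocardial_infarction", "stroke"))
}

#' Build an outcome-specific incident subcohort
#'
#' Constructs the analysis rows for one outcome: persons with no
#' occurrence in the lookback window `[T0 - lookback_days, T0)` (and, by
#' default, none in the acute window `(T0, T0 + landmark_days]`), followed
#' from `entry_date = T0 + landmark_days` until the earliest of the first
#' outcome occurrence, death (competing risk), or the group's
#' administrative end of follow-up. For a composite outcome the event is
#' the earliest component occurrence; a `"death"` component makes death an
#' event rather than a competing risk.
#'
#' @param cohort a landmark-filtered `pa_cohort` (see [apply_landmark()]).
#' @param outcome an outcome name present in the events table, or a name
#'   in `composites`.
#' @param spec the [cohort_spec()] used for the landmark filter.
#' @param composites named list of composite definitions
#'   (see [default_composites()]).
#' @return object of class `pa_subcohort`: a data frame with columns
#'   `person_id`, `group`, `care_setting`, `entry_date`, `time` (days from
#'   entry), `event`, `death` (competing-risk indicator; always 0 when
#'   death is an event component), plus attributes `outcome` and
#'   `exclusions`.
#' @export
build_subcohort <- function(cohort, outcome, spec = cohort_spec(),
                            composites = default_composites()) {
  p <- cohort$persons
  if (is.null(p$entry_date))
    stop("apply_landmark() must run before build_subcohort()", call. = FALSE)
  components <- if (outcome %in% names(composites)) composites[[outcome]]
                else outcome
  known <- unique(cohort$events$outcome)
  unknown <- setdiff(setdiff(components, "death"), known)
  if (length(unknown) && !outcome %in% names(composites) &&
      !outcome %in% known)
    stop("unknown outcome: ", outcome, call. = FALSE)
  death_is_event <- "death" %in% components
  ev_components <- setdiff(components, "death")

  ev <- cohort$events[cohort$events$outcome %in% ev_components, , drop = FALSE]
  # first occurrence per person across components
  first_ev <- rep(as.Date(NA), nrow(p))
  if (nrow(ev)) {
    agg <- tapply(as.numeric(ev$date), as.character(ev$person_id), min)
    idx <- match(names(agg), as.character(p$person_id))
    ok <- !is.na(idx)
    first_ev[idx[ok]] <- as.Date(unname(agg[ok]), origin = "1970-01-01")
  }
  if (death_is_event) {
    d <- p$death_date
    repl <- !is.na(d) & (is.na(first_ev) | d < first_ev)
    first_ev[repl] <- d[repl]
  }

  lb_start <- p$t0 - spec$lookback_days
  history <- !is.na(first_ev) & first_ev >= lb_start & first_ev < p$t0
  acute <- !is.na(first_ev) & first_ev >= p$t0 & first_ev <= p$entry_date
  drop_acute <- if (spec$acute_events == "exclude") acute else rep(FALSE, nrow(p))
  if (spec$acute_events == "ignore") first_ev[acute] <- NA
  keep <- !history & !drop_acute

  q <- p[keep, , drop = FALSE]
  first_ev <- first_ev[keep]
  eof <- group_end_of_followup(spec, q$group)
  death <- q$death_date
  if (death_is_event) death <- rep(as.Date(NA), nrow(q))

  exit <- eof
  exit <- pmin(exit, death, na.rm = TRUE)
  event <- !is.na(first_ev) & first_ev > q$entry_date & first_ev <= exit
  exit[event] <- first_ev[event]
  death_ind <- !event & !is.na(death) & death <= exit & death > q$entry_date
  time <- as.numeric(exit - q$entry_date)
  pos <- time > 0
  out <- data.frame(person_id = q$person_id[pos],
                    group = droplevels(q$group[pos]),
                    care_setting = q$care_setting[pos],
                    entry_date = q$entry_date[pos],
                    time = time[pos],
                    event = as.integer(event[pos]),
                    death = as.integer(death_ind[pos]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("pa_subcohort", "data.frame"),
            outcome = outcome,
            components = components,
            spec = spec,
            exclusions = c(history = sum(history),
                           acute_window = sum(drop_acute & !history),
                           zero_followup = sum(!pos)))
}

#' @export
print.pa_subcohort <- function(x, ...) {
  cat("Incident subcohort for outcome:", attr(x, "outcome"), "\n")
  tab <- table(x$group)
  ev <- tapply(x$event, x$group, sum)
  for (g in names(tab))
    cat(sprintf("  %-14s n = %6d, events = %5d, deaths (competing) = %5d\n",
                g, tab[[g]], ev[[g]], sum(x$death[x$group == g])))
  excl <- attr(x, "exclusions")
  cat("Excluded:", paste(names(excl), excl, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
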