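#' Partition persons by calendar-day parity of a date
#'
#' Deterministic negative-exposure device: persons are split by whether
#' the day-of-month of `date_field` is odd or even (e.g., receipt of
#' influenza vaccine on odd- versus even-numbered calendar days). Records
#' with a missing date are excluded and counted.
#'
#' @param persons data frame of persons.
#' @param date_field name of the `Date` column to split on.
#' @return list with `odd` and `even` (data frames) and `excluded_missing`
#'   (count).
#' @export
split_by_calendar_parity <- function(persons, date_field) {
  d <- persons[[date_field]]
  if (is.null(d)) stop("no column '", date_field, "'", call. = FALSE)
  miss <- is.na(d)
  day <- as.integer(format(d[!miss], "%d"))
  kept <- persons[!miss, , drop = FALSE]
  list(odd = kept[day %% 2L == 1L, , drop = FALSE],
       even = kept[day %% 2L == 0L, , drop = FALSE],
       excluded_missing = sum(miss))
}

#' Declare a control analysis and its a priori expectation
#'
#' @param kind `"positive_outcome"`, `"negative_outcome"` or
#'   `"negative_exposure"`.
#' @param outcome outcome name (for outcome controls) or the outcome to
#'   test under the substituted exposure (negative-exposure controls).
#' @param expected `"significant_gt1"` (the pipeline must flag an
#'   elevated, significant association) or `"nonsignificant"` (the 95\%
#'   CI must cover unity). Declared before estimation, per design.
#' @param exposure_rule for negative-exposure controls: name of the date
#'   column whose day-of-month parity defines the substitute exposure.
#' @return object of class `pa_control_spec`.
#' @export
control_spec <- function(kind = c("positive_outcome", "negative_outcome",
                                  "negative_exposure"),
                         outcome, expected = c("nonsignificant",
                                               "significant_gt1"),
                         exposure_rule = "vaccination_date") {
  structure(list(kind = match.arg(kind), outcome = outcome,
                 expected = match.arg(expected),
                 exposure_rule = exposure_rule),
            class = "pa_control_spec")
}

#' Run a battery of control analyses
#'
#' Each control reruns the identical pipeline — same cohort construction,
#' covariate handling and weighting — substituting only the outcome
#' (outcome controls) or the exposure definition (negative-exposure
#' controls, via day-of-month parity of a date), and records whether the
#' a priori expectation was met under the rule that a 95\% CI excluding
#' unity is significant. The configuration hash of the shared analysis
#' settings is logged for audit.
#'
#' @param cohort a `pa_cohort` with T0 assigned (landmark not yet
#'   applied).
#' @param specs list of [control_spec()] objects; every control must
#'   carry an expectation.
#' @param spec the [cohort_spec()] shared with the main analysis.
#' @param covariate_names covariates for weighting (default: the
#'   pre-defined set of the cohort).
#' @param comparison control group for outcome controls
#'   (default `"contemporary"`).
#' @param k_highdim high-dimensional codes to select per control (0
#'   skips selection, mirroring the predefined-only configuration).
#' @param min_count per-group minimum count for selection.
#' @return object of class `pa_battery`: data frame with columns
#'   `control`, `kind`, `hr`, `ci_low`, `ci_high`, `expected`, `met`;
#'   attribute `config_hash`.
#' @export
run_battery <- function(cohort, specs, spec = cohort_spec(),
                        covariate_names = predefined_covariates(cohort),
                        comparison = "contemporary",
                        k_highdim = 0L, min_count = 100L) {
  if (length(specs) == 0L) {
    return(structure(data.frame(control = character(0), kind = character(0),
                                hr = numeric(0), ci_low = numeric(0),
                                ci_high = numeric(0), expected = character(0),
                                met = logical(0)),
                     class = c("pa_battery", "data.frame"),
                     config_hash = config_hash(list(spec = spec,
                                                    covariates = covariate_names))))
  }
  bad <- vapply(specs, function(s) is.null(s$expected), logical(1))
  if (any(bad)) stop("every control needs a declared expectation", call. = FALSE)

  lm_cohort <- apply_landmark(cohort, spec)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    hz <- if (s$kind == "negative_exposure")
      control_parity_hazard(cohort, s, spec, covariate_names,
                            k_highdim, min_count)
    else
      analyze_outcome(lm_cohort, s$outcome, spec, covariate_names,
                      comparison = comparison, k_highdim = k_highdim,
                      min_count = min_count)$hazard
    met <- switch(s$expected,
                  nonsignificant = !hz$significant,
                  significant_gt1 = hz$significant && hz$hr > 1)
    rows[[i]] <- data.frame(control = s$outcome, kind = s$kind,
                            hr = hz$hr, ci_low = hz$ci95[1],
                            ci_high = hz$ci95[2], expected = s$expected,
                            met = met, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows),
            class = c("pa_battery", "data.frame"),
            config_hash = config_hash(list(spec = spec,
                                           covariates = covariate_names,
                                           k_highdim = k_highdim,
                                           min_count = min_count)))
}

# exposure substituted by calendar-day parity of a date; odd = "exposed"
control_parity_hazard <- function(cohort, s, spec, covariate_names,
                                  k_highdim, min_count) {
  p <- cohort$persons[cohort$persons$group != "historical", , drop = FALSE]
  halves <- split_by_calendar_parity(p, s$exposure_rule)
  p2 <- rbind(halves$odd, halves$even)
  day <- as.integer(format(p2[[s$exposure_rule]], "%d"))
  p2$group <- factor(ifelse(day %% 2L == 1L, "odd", "even"),
                     levels = c("odd", "even"))
  p2$t0 <- p2[[s$exposure_rule]]          # substitute index date
  # parity halves share the calendar era; reuse the contemporary follow-up end
  spec2 <- spec
  spec2$end_of_followup <- c(odd = unname(spec$end_of_followup["contemporary"]),
                             even = unname(spec$end_of_followup["contemporary"]))
  coh2 <- cohort
  coh2$persons <- p2
  coh2 <- apply_landmark(coh2, spec2)
  sc <- build_subcohort(coh2, s$outcome, spec2)
  w <- pipeline_weights(coh2, sc, covariate_names, k_highdim, min_count, spec2,
                        exposed_level = "odd", target_groups = c("odd", "even"))
  fit_weighted_cox(sc, w, exposed_level = "odd", comparison = "parity")
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.pa_battery <- function(x, ...) {
  cat("Control battery (", nrow(x), " controls, config ",
      substr(attr(x, "config_hash"), 1, 8), ")\n", sep = "")
  if (nrow(x)) {
    df <- x
    df$hr <- sprintf("%.3f (%.3f-%.3f)", df$hr, df$ci_low, df$ci_high)
    print.data.frame(df[, c("control", "kind", "hr", "expected", "met")],
                     row.names = FALSE)
    cat(sum(x$met), "of", nrow(x), "expectations met\n")
  }
  invisible(x)
}
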