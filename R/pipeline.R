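#' Restrict a cohort to the groups of one comparison
#'
#' Keeps the exposed group and the named control group (the contemporary
#' group is always retained as the target-population sample).
#'
#' @param cohort a `pa_cohort`.
#' @param comparison `"contemporary"` or `"historical"`.
#' @return the restricted cohort.
#' @export
restrict_comparison <- function(cohort, comparison = "contemporary") {
  keep_groups <- unique(c("exposed", "contemporary", comparison))
  keep <- cohort$persons$group %in% keep_groups
  cohort$persons <- cohort$persons[keep, , drop = FALSE]
  cohort
}

filter_subcohort <- function(subcohort, groups, care_setting = NULL,
                             exposed_level = "exposed") {
  keep <- subcohort$group %in% groups
  if (!is.null(care_setting))
    keep <- keep & (subcohort$group != exposed_level |
                    subcohort$care_setting == care_setting)
  out <- subcohort[keep, , drop = FALSE]
  out$group <- droplevels(out$group)
  for (a in c("outcome", "components", "spec", "exclusions"))
    attr(out, a) <- attr(subcohort, a)
  class(out) <- class(subcohort)
  out
}

#' Per-subcohort inverse-odds weights for a comparison
#'
#' Glue over the covariate and weighting modules: selects high-dimensional
#' codes within the subcohort (when `k_highdim > 0`), builds the design
#' matrix over the subcohort persons and the target-population sample,
#' and fits one propensity model per comparison side, returning
#' inverse-odds weights aligned with the subcohort rows.
#'
#' @param cohort the (landmark-filtered) `pa_cohort` supplying covariates
#'   and the target sample.
#' @param subcohort the `pa_subcohort` to weight (already restricted to
#'   the exposed group and one control group).
#' @param covariate_names pre-defined covariate columns.
#' @param k_highdim number of high-dimensional codes (0 = predefined
#'   only).
#' @param min_count per-group minimum count for code candidacy.
#' @param spec the [cohort_spec()] (lookback window for codes).
#' @param exposed_level,target_groups exposed side label and the group
#'   labels constituting the target-population sample.
#' @param truncate_quantile optional weight truncation quantile.
#' @param details when `TRUE` return a list with the weights, the
#'   subcohort design rows, groups and the selection (for balance
#'   reporting and doubly robust fits).
#' @return numeric weights (or a list when `details = TRUE`).
#' @export
pipeline_weights <- function(cohort, subcohort, covariate_names,
                             k_highdim = 0L, min_count = 100L,
                             spec = cohort_spec(),
                             exposed_level = "exposed",
                             target_groups = c("exposed", "contemporary"),
                             truncate_quantile = NULL,
                             details = FALSE) {
  p <- cohort$persons
  sub_rows <- match(as.character(subcohort$person_id),
                    as.character(p$person_id))
  target_rows <- which(as.character(p$group) %in% target_groups)
  all_rows <- union(sub_rows, target_rows)
  pers <- p[all_rows, , drop = FALSE]

  selection <- NULL
  if (k_highdim > 0L) {
    sp <- p[sub_rows, , drop = FALSE]
    sp$exposed <- subcohort$group == exposed_level
    selection <- rank_high_dim(sp, cohort$codes, min_count = min_count,
                               k = k_highdim,
                               lookback_days = spec$lookback_days)
  }
  dm <- build_design_matrix(pers, covariate_names, selection = selection,
                            codes = if (k_highdim > 0L) cohort$codes,
                            lookback_days = spec$lookback_days)
  sub_idx <- match(sub_rows, all_rows)
  tgt_idx <- match(target_rows, all_rows)
  x_target <- dm$x[tgt_idx, , drop = FALSE]

  # For a comparison side that is itself a constituent of the target
  # mixture, the density-ratio weight to the target has the closed form
  # pi_e / e(x) (exposed side) or (1 - pi_e) / (1 - e(x)) (other
  # constituent), with e(x) the exposure propensity *within* the target.
  # Its logit is linear when group membership follows logistic selection,
  # unlike the direct group-vs-mixture stack, whose log-odds is
  # intrinsically non-linear. Sides from outside the target (e.g., the
  # historical group) use the direct stack.
  tgt_exposed <- as.character(p$group[target_rows]) == exposed_level
  e_fit <- NULL
  if (any(tgt_exposed) && !all(tgt_exposed)) {
    keep_cols <- apply(x_target, 2L, function(col) stats::var(col) > 0)
    e_fit <- list(
      p = fit_propensity(x_target[, keep_cols, drop = FALSE],
                         as.numeric(tgt_exposed)),
      cols = keep_cols, pi_e = mean(tgt_exposed))
  }
  predict_e <- function(x) {
    beta <- attr(e_fit$p, "coefficients")
    beta[is.na(beta)] <- 0
    stats::plogis(drop(cbind(1, x[, e_fit$cols, drop = FALSE]) %*% beta))
  }

  w <- numeric(nrow(subcohort))
  prop <- numeric(nrow(subcohort))
  for (side in unique(as.character(subcohort$group))) {
    side_rows <- which(subcohort$group == side)
    x_side <- dm$x[sub_idx[side_rows], , drop = FALSE]
    if (side %in% target_groups && !is.null(e_fit)) {
      e <- predict_e(x_side)
      ws <- if (side == exposed_level) e_fit$pi_e / e
            else (1 - e_fit$pi_e) / (1 - e)
      if (!is.null(truncate_quantile))
        ws <- pmin(ws, stats::quantile(ws, truncate_quantile, type = 7))
      w[side_rows] <- ws
      prop[side_rows] <- ws / (1 + ws)   # implied target-membership scale
    } else {
      wt <- weight_to_target(x_side, x_target, truncate_quantile)
      w[side_rows] <- wt$weights
      prop[side_rows] <- wt$propensity
    }
  }
  if (!details) return(w)
  list(weights = w, propensity = prop,
       x = dm$x[sub_idx, , drop = FALSE], meta = dm$meta,
       groups = subcohort$group, selection = selection)
}

#' Analyze one outcome for one comparison
#'
#' Runs the estimation chain for a single outcome: incident subcohort,
#' optional care-setting restriction of the exposed side, optional
#' vaccination handling, per-side inverse-odds weighting (with optional
#' high-dimensional selection), weighted cause-specific Cox HR, and
#' optionally the weighted 12-month burdens and bootstrap excess burden.
#'
#' @param cohort a landmark-filtered `pa_cohort`.
#' @param outcome outcome or composite name.
#' @param spec the [cohort_spec()].
#' @param covariate_names pre-defined covariates for weighting.
#' @param comparison `"contemporary"` or `"historical"`.
#' @param care_setting optional care-setting level restricting the
#'   exposed side (`"non_hospitalized"`, `"hospitalized"`, `"icu"`).
#' @param k_highdim,min_count high-dimensional selection parameters.
#' @param doubly_robust also adjust for the covariates in the Cox model.
#' @param vaccination `"none"`, `"censor"` (censor at first dose) or
#'   `"time_varying"` (vaccination as a time-varying covariate).
#' @param burden_resamples bootstrap resamples for the excess burden
#'   (0 skips burden estimation).
#' @param horizon_days burden horizon.
#' @param seed seed for the burden bootstrap.
#' @param composites composite outcome definitions.
#' @param truncate_quantile optional weight truncation.
#' @return list with elements `hazard` (`pa_hazard`), `burden`
#'   (`pa_burden` or `NULL`), `balance` (`pa_balance`), `subcohort_n`.
#' @export
analyze_outcome <- function(cohort, outcome, spec = cohort_spec(),
                            covariate_names = predefined_covariates(cohort),
                            comparison = "contemporary",
                            care_setting = NULL,
                            k_highdim = 100L, min_count = 100L,
                            doubly_robust = FALSE,
                            vaccination = c("none", "censor", "time_varying"),
                            burden_resamples = 0L, horizon_days = 365,
                            seed = 1L, composites = default_composites(),
                            truncate_quantile = NULL) {
  vaccination <- match.arg(vaccination)
  sc <- build_subcohort(cohort, outcome, spec, composites)
  sc <- filter_subcohort(sc, c("exposed", comparison), care_setting)

  if (vaccination == "censor") {
    vd <- cohort$persons$vaccination_date
    names(vd) <- as.character(cohort$persons$person_id)
    sc <- censor_at(sc, vd[!is.na(vd)])
  }
  wd <- pipeline_weights(cohort, sc, covariate_names, k_highdim, min_count,
                         spec, truncate_quantile = truncate_quantile,
                         details = TRUE)
  hz <- if (vaccination == "time_varying") {
    vd <- cohort$persons$vaccination_date
    names(vd) <- as.character(cohort$persons$person_id)
    fit_time_varying(sc, wd$weights, vd[!is.na(vd)], comparison = comparison)
  } else {
    fit_weighted_cox(sc, wd$weights,
                     design_matrix = if (doubly_robust) wd$x,
                     comparison = comparison)
  }
  if (!is.null(care_setting)) hz$care_setting <- care_setting
  burden <- NULL
  if (burden_resamples > 0L)
    burden <- excess_burden(sc, wd$weights, horizon_days = horizon_days,
                            resamples = burden_resamples, seed = seed)
  bal <- balance_report(wd$x, sc$group == "exposed", wd$weights)
  list(hazard = hz, burden = burden, balance = bal, subcohort_n = nrow(sc))
}

#' Assemble a pipeline run configuration
#'
#' Collects every knob of an end-to-end run. All sensitivity variants are
#' expressible here: `k_highdim = 300` (expanded selection), `k_highdim =
#' 0` (pre-defined covariates only), `doubly_robust = TRUE`, and the
#' vaccination handling modes.
#'
#' @param comparison `"contemporary"` or `"historical"`.
#' @param outcomes outcomes/composites to analyze (`NULL`: all simulated
#'   outcomes).
#' @param care_setting_stratified also estimate within the mutually
#'   exclusive exposed care-setting strata.
#' @param k_highdim 100 (primary), 300 (sensitivity), or 0
#'   (predefined-only).
#' @param min_count minimum per-group code count (default 100).
#' @param doubly_robust apply covariates and weights to the Cox model.
#' @param vaccination_handling `"none"`, `"censor"` or `"time_varying"`.
#' @param did also run the difference-in-differences analysis.
#' @param burden_resamples bootstrap resamples for excess burdens
#'   (0 skips burdens).
#' @param seed master seed: every stage derives its stream from it.
#' @param sim a [sim_config()] for cohort generation (its own seed is
#'   overridden by `seed`).
#' @param spec a [cohort_spec()].
#' @param composites composite outcome definitions.
#' @param truncate_quantile optional weight truncation quantile.
#' @param output_dir optional directory for [write_results()].
#' @return object of class `pa_run_config`.
#' @export
run_config <- function(comparison = c("contemporary", "historical"),
                       outcomes = NULL,
                       care_setting_stratified = FALSE,
                       k_highdim = 100L, min_count = 100L,
                       doubly_robust = FALSE,
                       vaccination_handling = c("none", "censor",
                                                "time_varying"),
                       did = FALSE,
                       burden_resamples = 0L,
                       seed = 1L,
                       sim = sim_config(),
                       spec = cohort_spec(),
                       composites = default_composites(),
                       truncate_quantile = NULL,
                       output_dir = NULL) {
  if (k_highdim < 0) stop("k_highdim must be >= 0", call. = FALSE)
  structure(list(comparison = match.arg(comparison),
                 outcomes = outcomes,
                 care_setting_stratified = isTRUE(care_setting_stratified),
                 k_highdim = as.integer(k_highdim),
                 min_count = as.integer(min_count),
                 doubly_robust = isTRUE(doubly_robust),
                 vaccination_handling = match.arg(vaccination_handling),
                 did = isTRUE(did),
                 burden_resamples = as.integer(burden_resamples),
                 seed = as.integer(seed),
                 sim = sim, spec = spec, composites = composites,
                 truncate_quantile = truncate_quantile,
                 output_dir = output_dir),
            class = "pa_run_config")
}

#' Read a run configuration from a structured text file
#'
#' Reads a YAML file whose top-level keys are arguments of [run_config()];
#' `sim` and `spec` sub-maps are passed to [sim_config()] and
#' [cohort_spec()].
#'
#' @param path YAML file path.
#' @return a `pa_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    y$sim$true_log_hr <- unlist(y$sim$true_log_hr)
    y$sim$baseline_hazard <- unlist(y$sim$baseline_hazard)
    y$sim <- do.call(sim_config, y$sim)
  }
  if (!is.null(y$spec)) {
    if (!is.null(y$spec$end_of_followup))
      y$spec$end_of_followup <- unlist(y$spec$end_of_followup)
    y$spec <- do.call(cohort_spec, y$spec)
  }
  do.call(run_config, y)
}

#' Execute the full pipeline
#'
#' simulate (unless a cohort is supplied) -> assign control T0 ->
#' landmark -> per outcome: incident subcohort, high-dimensional
#' selection, inverse-odds weighting, weighted cause-specific Cox,
#' burdens, optional care-setting strata and difference-in-differences.
#' Identical configuration and seed reproduce byte-identical result
#' tables.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-generated `pa_cohort` (skips simulation).
#' @return object of class `pa_run`: list with `results` (tidy data
#'   frame), `did` (data frame or `NULL`), `balance` (per-outcome list),
#'   `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pa_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(cohort)) {
    sim <- config$sim
    sim$seed <- config$seed
    cohort <- stage("simulate", generate_cohort(sim))
  }
  n_input <- nrow(cohort$persons)
  cohort <- stage("assign_t0", assign_t0(cohort, config$spec,
                                         seed = config$seed + 101L))
  cohort <- stage("landmark", apply_landmark(cohort, config$spec))
  outcomes <- config$outcomes
  if (is.null(outcomes)) outcomes <- sim_outcomes(cohort$config)
  covs <- predefined_covariates(cohort)

  strata <- list(list(label = "all", cs = NULL))
  if (config$care_setting_stratified)
    strata <- c(strata, lapply(c("non_hospitalized", "hospitalized", "icu"),
                               function(s) list(label = s, cs = s)))

  rows <- list(); balances <- list(); did_rows <- list()
  for (oc in outcomes) {
    for (st in strata) {
      res <- stage(paste0("estimate:", oc, ":", st$label),
                   analyze_outcome(cohort, oc, config$spec, covs,
                                   comparison = config$comparison,
                                   care_setting = st$cs,
                                   k_highdim = config$k_highdim,
                                   min_count = config$min_count,
                                   doubly_robust = config$doubly_robust,
                                   vaccination = config$vaccination_handling,
                                   burden_resamples = config$burden_resamples,
                                   seed = config$seed + 211L,
                                   composites = config$composites,
                                   truncate_quantile = config$truncate_quantile))
      hz <- res$hazard; bd <- res$burden
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, comparison = config$comparison,
        care_setting = st$label,
        n_exposed = hz$n_exposed, n_control = hz$n_control,
        events = hz$events,
        hr = hz$hr, ci_low = hz$ci95[1], ci_high = hz$ci95[2],
        significant = hz$significant,
        burden_exposed = if (is.null(bd)) NA_real_ else bd$burden_exposed,
        burden_control = if (is.null(bd)) NA_real_ else bd$burden_control,
        excess_burden = if (is.null(bd)) NA_real_ else bd$excess_burden,
        excess_ci_low = if (is.null(bd)) NA_real_ else bd$excess_burden_ci95[1],
        excess_ci_high = if (is.null(bd)) NA_real_ else bd$excess_burden_ci95[2],
        max_abs_smd_after = attr(res$balance, "max_abs_smd_after"),
        stringsAsFactors = FALSE)
      if (st$label == "all")
        balances[[oc]] <- res$balance
    }
    if (config$did) {
      dd <- stage(paste0("did:", oc),
                  did_for_outcome(cohort, oc, config, covs))
      did_rows[[length(did_rows) + 1L]] <- data.frame(
        outcome = oc, comparison = config$comparison,
        irr_pre = dd$irr_pre, irr_post = dd$irr_post,
        ratio_of_irr = dd$ratio_of_irr,
        ratio_ci_low = dd$ci95[1], ratio_ci_high = dd$ci95[2],
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  manifest <- list(package = "postacute",
                   version = as.character(utils::packageVersion("postacute")),
                   seed = config$seed,
                   comparison = config$comparison,
                   k_highdim = config$k_highdim,
                   doubly_robust = config$doubly_robust,
                   vaccination_handling = config$vaccination_handling,
                   n_input_persons = n_input,
                   n_after_landmark = nrow(cohort$persons),
                   landmark_exclusions = as.list(attr(cohort, "exclusions")),
                   outcomes = outcomes,
                   config_hash = config_hash(config))
  run <- structure(list(results = results,
                        did = if (length(did_rows)) do.call(rbind, did_rows),
                        balance = balances,
                        manifest = manifest),
                   class = "pa_run")
  if (!is.null(config$output_dir)) write_results(run, config$output_dir)
  run
}

# DiD chain for one outcome: matched pre-period, post subcohort as the
# post period, weights from pre-exposure covariates, joint bootstrap CI
did_for_outcome <- function(cohort, outcome, config, covs) {
  spec <- config$spec
  sc <- build_subcohort(cohort, outcome, spec, config$composites)
  sc <- filter_subcohort(sc, c("exposed", config$comparison))
  post_w <- pipeline_weights(cohort, sc, covs, config$k_highdim,
                             config$min_count, spec,
                             truncate_quantile = config$truncate_quantile)
  post <- as_period(sc)

  pre <- build_pre_period(cohort, outcome, spec, config$composites)
  pre <- pre[pre$group %in% c("exposed", config$comparison), , drop = FALSE]
  pre$group <- droplevels(pre$group)
  pre_sc <- pre  # reuse the weighting glue through a subcohort-shaped frame
  pre_w <- pipeline_weights(cohort, pre_sc, covs, config$k_highdim,
                            config$min_count, spec,
                            truncate_quantile = config$truncate_quantile)
  did_estimate(pre, post, pre_w, post_w,
               resamples = max(config$burden_resamples, 500L),
               seed = config$seed + 307L)
}

#' @export
print.pa_run <- function(x, ...) {
  cat("Pipeline run (comparison:", x$manifest$comparison,
      "| k_highdim:", x$manifest$k_highdim, ")\n")
  df <- x$results
  df$hr <- sprintf("%.2f (%.2f-%.2f)", df$hr, df$ci_low, df$ci_high)
  print.data.frame(df[, c("outcome", "care_setting", "n_exposed",
                          "events", "hr", "significant")],
                   row.names = FALSE)
  if (!is.null(x$did)) {
    cat("Difference-in-differences:\n")
    print.data.frame(x$did, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write the tidy result tables of a run
#'
#' Writes `results.tsv`, `did.tsv` (when present), `balance_<outcome>.tsv`
#' and `manifest.yaml` into `dir`. Output is deterministic: identical
#' config + seed give byte-identical files.
#'
#' @param run a `pa_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wr(run$results, "results.tsv")
  if (!is.null(run$did)) wr(run$did, "did.tsv")
  for (oc in names(run$balance))
    wr(as.data.frame(run$balance[[oc]]), paste0("balance_", oc, ".tsv"))
  yaml::write_yaml(run$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Subgroup analyses
#'
#' Reruns the full estimation chain (selection, weighting, Cox) within
#' each subgroup. A subgroup in which the model is inestimable (no
#' persons, or no events on a side) is reported with `inestimable = TRUE`
#' rather than dropped.
#'
#' @param cohort a landmark-filtered `pa_cohort`.
#' @param subgroup_defs named list; each element is a function taking the
#'   persons data frame and returning a logical row filter.
#' @param outcome outcome to analyze.
#' @param config a [run_config()].
#' @return data frame with one row per subgroup: hr, ci, n, or an
#'   inestimable marker.
#' @export
subgroup_analysis <- function(cohort, subgroup_defs, outcome, config) {
  covs <- predefined_covariates(cohort)
  rows <- lapply(names(subgroup_defs), function(nm) {
    keep <- subgroup_defs[[nm]](cohort$persons)
    sub <- cohort
    sub$persons <- cohort$persons[keep, , drop = FALSE]
    res <- tryCatch(
      analyze_outcome(sub, outcome, config$spec, covs,
                      comparison = config$comparison,
                      k_highdim = config$k_highdim,
                      min_count = config$min_count,
                      composites = config$composites),
      error = function(e) NULL)
    if (is.null(res))
      data.frame(subgroup = nm, n = sum(keep), hr = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 inestimable = TRUE, stringsAsFactors = FALSE)
    else
      data.frame(subgroup = nm, n = res$subcohort_n, hr = res$hazard$hr,
                 ci_low = res$hazard$ci95[1], ci_high = res$hazard$ci95[2],
                 inestimable = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Minimal forest plot of a run's hazard ratios
#'
#' @param x a `pa_run`.
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.pa_run <- function(x, ...) {
  df <- x$results
  lab <- paste(df$outcome, ifelse(df$care_setting == "all", "",
                                  paste0("[", df$care_setting, "]")))
  n <- nrow(df)
  graphics::plot(df$hr, seq_len(n), xlim = range(c(df$ci_low, df$ci_high, 1)),
                 log = "x", pch = 15, yaxt = "n", xlab = "Hazard ratio",
                 ylab = "", main = "Adjusted hazard ratios (95% CI)")
  graphics::segments(df$ci_low, seq_len(n), df$ci_high, seq_len(n))
  graphics::abline(v = 1, lty = 2, col = "grey40")
  graphics::axis(2, at = seq_len(n), labels = lab, las = 2, cex.axis = 0.7)
  invisible(x)
}
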