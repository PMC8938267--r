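#' Fit the target-population propensity model
#'
#' Main-effects logistic regression of target-population membership on the
#' covariates, over rows pooled from a comparison group and a sample of
#' the target population. Returns the fitted membership probabilities.
#' Perfect or quasi-perfect separation (fitted probabilities within 1e-8
#' of 0 or 1) aborts with a diagnostic naming the covariate columns with
#' extreme coefficients.
#'
#' @param design_matrix numeric matrix, one row per pooled person.
#' @param target_membership_labels binary vector (1 = target-population
#'   row, 0 = comparison-group row).
#' @return numeric vector of probabilities in (0, 1), plus the fitted
#'   `glm` coefficients in `attr(, "coefficients")`.
#' @export
fit_propensity <- function(design_matrix, target_membership_labels) {
  y <- as.numeric(target_membership_labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both membership classes must be present", call. = FALSE)
  fit <- stats::glm.fit(cbind(`(Intercept)` = 1, design_matrix), y,
                        family = stats::binomial())
  p <- fit$fitted.values
  if (any(p < 1e-8 | p > 1 - 1e-8)) {
    cf <- fit$coefficients[-1L]
    bad <- names(cf)[!is.na(cf) & abs(cf) > 10]
    stop("propensity model separates the classes; suspect columns: ",
         paste(if (length(bad)) bad else "(none with |coef| > 10)",
               collapse = ", "), call. = FALSE)
  }
  structure(p, coefficients = fit$coefficients)
}

#' Inverse-odds weights from propensities
#'
#' The weight standardizing a comparison group to the target population is
#' the odds of target membership, `w = p / (1 - p)`. Optional truncation
#' caps weights at an upper quantile; the default applies none.
#'
#' @param propensities probabilities strictly inside (0, 1).
#' @param truncate_quantile e.g. 0.995 to cap at the 99.5th percentile;
#'   `NULL` (default) leaves weights untouched.
#' @return numeric weight vector.
#' @export
compute_weights <- function(propensities, truncate_quantile = NULL) {
  p <- as.numeric(propensities)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("propensities must lie strictly inside (0, 1)", call. = FALSE)
  w <- p / (1 - p)
  if (!is.null(truncate_quantile)) {
    cap <- stats::quantile(w, truncate_quantile, type = 7)
    w <- pmin(w, cap)
  }
  w
}

#' Standardized mean difference between two groups
#'
#' `(m1 - m2) / sqrt((s1^2 + s2^2) / 2)` where the means are weighted when
#' weights are supplied and the pooled SD is always computed unweighted
#' from the raw sample, so before/after-weighting comparisons share a
#' denominator. Indicator covariates (values in \{0, 1\}) use the binomial
#' variance `p(1 - p)`. When the pooled SD is zero the SMD is 0 if the
#' means agree and an error otherwise.
#'
#' @param covariate numeric vector.
#' @param groups two-level vector; the first level (or `TRUE`) is group 1.
#' @param weights optional nonnegative weights (unweighted when `NULL`).
#' @return a single number.
#' @export
standardized_mean_difference <- function(covariate, groups, weights = NULL) {
  g <- if (is.logical(groups)) factor(groups, levels = c(TRUE, FALSE))
       else as.factor(groups)
  lv <- levels(droplevels(g))
  if (length(lv) != 2L) stop("exactly two groups required", call. = FALSE)
  i1 <- g == lv[1L]; i2 <- g == lv[2L]
  if (is.null(weights)) weights <- rep(1, length(covariate))
  wm <- function(idx) sum(weights[idx] * covariate[idx]) / sum(weights[idx])
  m1 <- wm(i1); m2 <- wm(i2)
  binary <- all(covariate %in% c(0, 1))
  v <- function(idx) {
    if (binary) { p <- mean(covariate[idx]); p * (1 - p) }
    else stats::var(covariate[idx])
  }
  pooled <- sqrt((v(i1) + v(i2)) / 2)
  if (pooled == 0) {
    if (isTRUE(all.equal(m1, m2))) return(0)
    stop("zero pooled SD with unequal means", call. = FALSE)
  }
  (m1 - m2) / pooled
}

#' Covariate balance report before and after weighting
#'
#' @param design_matrix numeric matrix of covariate columns.
#' @param groups two-level group vector aligned with the rows.
#' @param weights weights to assess (per-person, aligned).
#' @return object of class `pa_balance`: data frame with columns
#'   `covariate`, `smd_before`, `smd_after`, plus attribute
#'   `max_abs_smd_after`.
#' @export
balance_report <- function(design_matrix, groups, weights) {
  res <- data.frame(covariate = colnames(design_matrix),
                    smd_before = NA_real_, smd_after = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(design_matrix))) {
    x <- design_matrix[, j]
    if (stats::var(x) == 0) next                 # constant column: no contrast
    res$smd_before[j] <- standardized_mean_difference(x, groups)
    res$smd_after[j] <- standardized_mean_difference(x, groups, weights)
  }
  structure(res, class = c("pa_balance", "data.frame"),
            max_abs_smd_after = max(abs(res$smd_after), na.rm = TRUE))
}

#' @export
print.pa_balance <- function(x, ...) {
  cat("Covariate balance (standardized mean differences)\n")
  print.data.frame(utils::head(x[order(-abs(x$smd_after)), ], 10),
                   row.names = FALSE, digits = 3)
  cat("max |SMD| after weighting:",
      format(attr(x, "max_abs_smd_after"), digits = 3), "\n")
  invisible(x)
}

#' Inverse-odds weights standardizing a group to a target population
#'
#' Stacks the comparison-group rows (label 0) with the target-population
#' rows (label 1), fits the propensity model on the pooled design matrix,
#' and returns the inverse-odds weight for each comparison-group person.
#' Persons may legitimately appear on both sides (the target population
#' can contain the comparison group).
#'
#' @param x_group design-matrix rows of the comparison group.
#' @param x_target design-matrix rows of the target-population sample.
#' @param truncate_quantile passed to [compute_weights()].
#' @return list with `weights`, `propensity` (both per comparison-group
#'   row, in order) and the propensity model `coefficients`.
#' @export
weight_to_target <- function(x_group, x_target, truncate_quantile = NULL) {
  stopifnot(ncol(x_group) == ncol(x_target))
  x <- rbind(x_group, x_target)
  y <- c(rep(0, nrow(x_group)), rep(1, nrow(x_target)))
  # drop constant columns: they carry no information and break the fit
  keep <- apply(x, 2L, function(col) stats::var(col) > 0)
  p <- fit_propensity(x[, keep, drop = FALSE], y)
  pg <- p[seq_len(nrow(x_group))]
  list(weights = compute_weights(pg, truncate_quantile),
       propensity = as.numeric(pg),
       coefficients = attr(p, "coefficients"))
}
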