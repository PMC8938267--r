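#' Conditional mean imputation within exposure group
#'
#' Missing entries of a numeric covariate are replaced by the mean of the
#' observed values in the same group; factors/characters take the
#' within-group mode (a mean is undefined for categories). Observed
#' entries are never altered.
#'
#' @param values numeric vector, factor or character vector with `NA`s.
#' @param group_labels grouping vector of the same length.
#' @return `values` with `NA`s filled in.
#' @export
impute_conditional_mean <- function(values, group_labels) {
  stopifnot(length(values) == length(group_labels))
  if (!anyNA(values)) return(values)
  for (g in unique(group_labels)) {
    rows <- which(group_labels == g)
    obs <- values[rows][!is.na(values[rows])]
    if (length(obs) == 0L)
      stop("group '", g, "' has no observed values to impute from", call. = FALSE)
    fill <- if (is.numeric(values)) mean(obs)
            else names(sort(table(as.character(obs)), decreasing = TRUE))[1L]
    miss <- rows[is.na(values[rows])]
    values[miss] <- fill
  }
  values
}

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline in Harrell's normalization:
#' cubic between the boundary knots, constrained linear beyond them. With
#' `k` knots \eqn{t_1 < \dots < t_k} the basis has `k - 1` columns, the
#' first being `x` itself and, for `j = 1, ..., k - 2`,
#' \deqn{b_{j+1}(x) = \frac{(x-t_j)_+^3 - (x-t_{k-1})_+^3
#'   \frac{t_k - t_j}{t_k - t_{k-1}} + (x-t_k)_+^3
#'   \frac{t_{k-1} - t_j}{t_k - t_{k-1}}}{(t_k - t_1)^2}.}
#'
#' @param x numeric vector without `NA`s.
#' @param n_knots number of knots (>= 3); ignored when `knots` is given.
#' @param knots optional explicit knot locations.
#' @param quantiles knot placement quantiles when `knots` is `NULL`;
#'   defaults to an even spread with outer knots at 0.05/0.95 (for 4
#'   knots: 0.05, 0.35, 0.65, 0.95).
#' @return matrix with `length(knots) - 1` columns and a `"knots"`
#'   attribute.
#' @export
spline_basis <- function(x, n_knots = 4L, knots = NULL, quantiles = NULL) {
  if (anyNA(x)) stop("x must not contain NA; impute first", call. = FALSE)
  if (is.null(knots)) {
    if (n_knots < 3L) stop("n_knots must be >= 3", call. = FALSE)
    if (length(unique(x)) < n_knots)
      stop("need >= 3 distinct knots and at least as many distinct x values",
           call. = FALSE)
    if (is.null(quantiles))
      quantiles <- seq(0.05, 0.95, length.out = n_knots)
    knots <- unname(stats::quantile(x, quantiles, type = 7))
  }
  knots <- sort(unique(knots))
  k <- length(knots)
  if (k < 3L)
    stop("need >= 3 distinct knots", call. = FALSE)
  pos3 <- function(u) pmax(u, 0)^3
  scale <- (knots[k] - knots[1L])^2
  b <- matrix(0, length(x), k - 1L)
  b[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    b[, j + 1L] <- (pos3(x - knots[j]) -
                    pos3(x - knots[k - 1L]) * (knots[k] - knots[j]) /
                      (knots[k] - knots[k - 1L]) +
                    pos3(x - knots[k]) * (knots[k - 1L] - knots[j]) /
                      (knots[k] - knots[k - 1L])) / scale
  }
  colnames(b) <- paste0("rcs", seq_len(k - 1L))
  attr(b, "knots") <- knots
  b
}

#' Rank high-dimensional codes by univariate relative risk
#'
#' Implements the algorithmic covariate-selection step: among codes
#' occurring in at least `min_count` persons *within each* exposure group
#' during the lookback window, the univariate relative risk of the code
#' with respect to exposure is computed (prevalence among exposed divided
#' by prevalence among controls, with a 0.5 continuity correction applied
#' to zero cells), and the `k` codes with the strongest association are
#' selected. "Strongest" defaults to largest `|log RR|`, so protective
#' and risk-elevating codes both qualify; set `ranking = "raw"` to rank
#' by RR itself. Ties break lexicographically by (domain, code), making
#' the selection invariant to row order.
#'
#' @param persons data frame with `person_id`, `t0` and a logical/2-level
#'   `exposed` indicator column, or a factor `group` where `"exposed"`
#'   marks the exposed side.
#' @param codes long-format code table (`person_id`, `domain`, `code`,
#'   `date`).
#' @param min_count minimum per-group person count (default 100).
#' @param k number of codes to select (default 100).
#' @param lookback_days ascertainment window before T0 (default 365).
#' @param ranking `"abs_log"` (default) or `"raw"`.
#' @return object of class `pa_hd_selection`: list with `candidates`
#'   (data frame: domain, code, count_exposed, count_control, rr, rank),
#'   `selected` (character vector of codes, strongest first), `k`,
#'   `min_count`.
#' @export
rank_high_dim <- function(persons, codes, min_count = 100L, k = 100L,
                          lookback_days = 365L,
                          ranking = c("abs_log", "raw")) {
  ranking <- match.arg(ranking)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  exposed <- if (!is.null(persons$exposed)) as.logical(persons$exposed)
             else persons$group == "exposed"
  n1 <- sum(exposed); n0 <- sum(!exposed)
  if (n1 == 0L || n0 == 0L)
    stop("both exposure groups must be non-empty", call. = FALSE)

  empty <- data.frame(domain = character(0), code = character(0),
                      count_exposed = integer(0), count_control = integer(0),
                      rr = numeric(0), rank = integer(0))
  sel <- function(cand) structure(list(candidates = cand,
                                       selected = cand$code[order(cand$rank)],
                                       k = k, min_count = min_count),
                                  class = "pa_hd_selection")
  if (nrow(codes) == 0L) return(sel(empty))

  idx <- match(as.character(codes$person_id), as.character(persons$person_id))
  keep <- !is.na(idx)
  t0 <- persons$t0[idx[keep]]
  in_window <- codes$date[keep] >= (t0 - lookback_days) & codes$date[keep] < t0
  cw <- codes[keep, , drop = FALSE][in_window, , drop = FALSE]
  exp_w <- exposed[idx[keep]][in_window]
  if (nrow(cw) == 0L) return(sel(empty))

  key <- paste(cw$domain, cw$code, sep = "\r")
  pid <- as.character(cw$person_id)
  dup <- duplicated(paste(key, pid))            # person counted once per code
  key <- key[!dup]; exp_w <- exp_w[!dup]
  c1 <- tapply(exp_w, key, sum)
  ct <- tapply(exp_w, key, length)
  c0 <- ct - c1
  parts <- do.call(rbind, strsplit(names(c1), "\r", fixed = TRUE))
  cand <- data.frame(domain = parts[, 1L], code = parts[, 2L],
                     count_exposed = as.integer(c1),
                     count_control = as.integer(c0),
                     stringsAsFactors = FALSE)
  cand <- cand[cand$count_exposed >= min_count &
               cand$count_control >= min_count, , drop = FALSE]
  if (nrow(cand) == 0L) return(sel(empty))

  a <- cand$count_exposed; b <- cand$count_control
  zero <- a == 0L | b == 0L
  corr <- ifelse(zero, 0.5, 0)                  # continuity correction
  cand$rr <- ((a + corr) / (n1 + corr)) / ((b + corr) / (n0 + corr))
  strength <- if (ranking == "abs_log") abs(log(cand$rr)) else cand$rr
  ord <- order(-strength, cand$domain, cand$code)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  res <- sel(cand)
  res$selected <- utils::head(cand$code, k)
  res
}

#' @export
print.pa_hd_selection <- function(x, ...) {
  cat("High-dimensional covariate selection:", nrow(x$candidates),
      "candidates passed min_count =", x$min_count, "\n")
  cat("Selected", length(x$selected), "of k =", x$k, "\n")
  if (nrow(x$candidates)) print(utils::head(x$candidates, 10))
  invisible(x)
}

#' Names of the pre-defined covariates of a simulated cohort
#' @param cohort a `pa_cohort`.
#' @return character vector of covariate column names in `persons`.
#' @export
predefined_covariates <- function(cohort) {
  base <- c("age", "race", "sex", "adi", "bmi", "smoking",
            "outpatient_count", "inpatient_count", "long_term_care",
            "cancer", "ckd", "chronic_lung_disease", "dementia", "diabetes",
            "dysautonomia", "hyperlipidemia", "hypertension",
            "egfr", "sbp", "dbp")
  conf <- grep("^x[0-9]+$", names(cohort$persons), value = TRUE)
  c(base[base %in% names(cohort$persons)], conf)
}

#' Build the analysis design matrix
#'
#' One row per person: continuous covariates are imputed by conditional
#' group mean and expanded to restricted cubic spline bases (knots from
#' the pooled sample); binary and categorical covariates are
#' mode-imputed, categoricals expanded to reference-coded indicators;
#' selected high-dimensional codes enter as 0/1 occurrence indicators for
#' the lookback window. Errors if any missing value survives imputation.
#'
#' @param persons data frame of persons (with `t0` when codes are used).
#' @param covariate_names columns of `persons` to include.
#' @param selection optional `pa_hd_selection` from [rank_high_dim()].
#' @param codes long code table (required when `selection` selects codes).
#' @param n_knots spline knots for continuous covariates (default 4).
#' @param lookback_days code ascertainment window (default 365).
#' @param spline logical: expand continuous covariates to spline bases
#'   (`TRUE`, default) or keep them linear.
#' @return list with `x` (numeric matrix), `meta` (data frame: column,
#'   source covariate, type) and `knots` (named list).
#' @export
build_design_matrix <- function(persons, covariate_names,
                                selection = NULL, codes = NULL,
                                n_knots = 4L, lookback_days = 365L,
                                spline = TRUE) {
  n <- nrow(persons)
  group <- if (!is.null(persons$group)) persons$group else rep(1L, n)
  cols <- list(); meta <- list(); knots <- list()
  add <- function(mat, source, type) {
    cols[[length(cols) + 1L]] <<- mat
    meta[[length(meta) + 1L]] <<- data.frame(column = colnames(mat),
                                             source = source, type = type,
                                             stringsAsFactors = FALSE)
  }
  for (v in covariate_names) {
    val <- impute_conditional_mean(persons[[v]], group)
    if (is.numeric(val)) {
      if (length(unique(val)) <= 2L) {            # flags stay single columns
        mat <- matrix(as.numeric(val), ncol = 1,
                      dimnames = list(NULL, v))
        add(mat, v, "flag")
      } else if (spline && length(unique(val)) >= n_knots + 1L &&
                 length(unique(stats::quantile(val,
                   seq(0.05, 0.95, length.out = n_knots), type = 7))) >= 3L) {
        # skewed counts can collapse the quantile knots; fall back to linear
        b <- spline_basis(val, n_knots = n_knots)
        colnames(b) <- paste0(v, "_", colnames(b))
        knots[[v]] <- attr(b, "knots")
        add(b, v, "spline")
      } else {
        add(matrix(val, ncol = 1, dimnames = list(NULL, v)), v, "linear")
      }
    } else {
      f <- droplevels(as.factor(val))
      if (nlevels(f) < 2L) next                   # constant: nothing to encode
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(v, "_", levels(f)[-1L])
      add(mm, v, "indicator")
    }
  }
  if (!is.null(selection) && length(selection$selected)) {
    if (is.null(codes))
      stop("codes table required when selection includes codes", call. = FALSE)
    code_mat <- matrix(0, n, length(selection$selected),
                       dimnames = list(NULL, paste0("code_", selection$selected)))
    idx <- match(as.character(codes$person_id), as.character(persons$person_id))
    keep <- !is.na(idx)
    t0 <- persons$t0[idx[keep]]
    in_w <- codes$date[keep] >= (t0 - lookback_days) & codes$date[keep] < t0
    cw <- codes[keep, , drop = FALSE][in_w, , drop = FALSE]
    ridx <- idx[keep][in_w]
    cmatch <- match(cw$code, selection$selected)
    ok <- !is.na(cmatch)
    code_mat[cbind(ridx[ok], cmatch[ok])] <- 1
    add(code_mat, "high_dim", "code")
  }
  x <- do.call(cbind, cols)
  if (anyNA(x)) stop("design matrix contains missing values after imputation",
                     call. = FALSE)
  list(x = x, meta = do.call(rbind, meta), knots = knots)
}
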