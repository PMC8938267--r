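test_that("conditional mean imputation fills by group mean", {
  x <- c(1, 3, NA, 10, NA, 20)
  g <- c("a", "a", "a", "b", "b", "b")
  out <- impute_conditional_mean(x, g)
  expect_equal(out, c(1, 3, 2, 10, 15, 20))
  expect_identical(impute_conditional_mean(c(1, 2), c("a", "a")), c(1, 2))
  expect_error(impute_conditional_mean(c(1, NA), c("a", "b")),
               "no observed values")
  # categorical: within-group mode
  f <- c("x", "x", NA, "y", "y", NA)
  expect_equal(impute_conditional_mean(f, g), c("x", "x", "x", "y", "y", "y"))
})

test_that("restricted cubic spline basis follows the truncated-power formula", {
  set.seed(1)
  x <- c(seq(0, 10, length.out = 50), 2.5, 7.7)
  b3 <- spline_basis(x, n_knots = 3)
  expect_equal(ncol(b3), 2L)
  expect_equal(b3[, 1], x)                        # linear term is x itself

  knots <- c(1, 4, 6, 9)
  b <- spline_basis(x, knots = knots)
  expect_equal(ncol(b), 3L)
  # independent brute-force evaluation of the textbook formula
  pp <- function(u) pmax(u, 0)^3
  k <- 4
  for (j in 1:2) {
    ref <- (pp(x - knots[j]) -
            pp(x - knots[k - 1]) * (knots[k] - knots[j]) /
              (knots[k] - knots[k - 1]) +
            pp(x - knots[k]) * (knots[k - 1] - knots[j]) /
              (knots[k] - knots[k - 1])) / (knots[k] - knots[1])^2
    expect_equal(unname(b[, j + 1]), ref)
  }
  # linearity beyond the boundary knots: second differences vanish
  xs <- c(11, 12, 13)
  bt <- spline_basis(xs, knots = knots)
  expect_equal(diff(diff(bt[, 2])), 0, tolerance = 1e-10)

  expect_error(spline_basis(c(1, 1, 2), n_knots = 4), "distinct")
})

test_that("rcs column space agrees with a natural cubic spline fit", {
  set.seed(7)
  x <- runif(300, 0, 10)
  y <- sin(x) + rnorm(300, 0, 0.1)
  knots <- unname(quantile(x, c(0.05, 0.35, 0.65, 0.95)))
  b <- spline_basis(x, knots = knots)
  fit_rcs <- lm(y ~ b)
  fit_ns <- lm(y ~ splines::ns(x, knots = knots[2:3],
                               Boundary.knots = knots[c(1, 4)]))
  # same function space => identical fitted values
  expect_equal(unname(fitted(fit_rcs)), unname(fitted(fit_ns)),
               tolerance = 1e-8)
})

test_that("high-dimensional ranking reproduces hand-computed relative risks", {
  t0 <- as.Date("2020-06-01")
  n1 <- 10; n0 <- 20
  persons <- data.frame(person_id = 1:30,
                        exposed = rep(c(TRUE, FALSE), c(n1, n0)),
                        t0 = t0)
  mk <- function(code, ids) data.frame(person_id = ids, domain = "diagnosis",
                                       code = code, date = t0 - 30)
  # hand 2x2 tables: RR_a = (5/10)/(5/20) = 2.0; RR_b = (3/10)/(4/20) = 1.5;
  # RR_c = (1/10)/(8/20) = 0.25
  codes <- rbind(mk("a", c(1:5, 11:15)),
                 mk("b", c(1:3, 11:14)),
                 mk("c", c(1, 11:18)))
  sel <- rank_high_dim(persons, codes, min_count = 1, k = 2)
  rr <- setNames(sel$candidates$rr, sel$candidates$code)
  expect_equal(rr[["a"]], 2.0)
  expect_equal(rr[["b"]], 1.5)
  expect_equal(rr[["c"]], 0.25)
  # |log RR| ranking: 0.25 (|log|=1.39) then 2.0 (0.69); b dropped at k = 2
  expect_equal(sel$selected, c("c", "a"))
  # raw ranking instead selects the largest RRs
  sel_raw <- rank_high_dim(persons, codes, min_count = 1, k = 2,
                           ranking = "raw")
  expect_equal(sel_raw$selected, c("a", "b"))

  # min_count boundary: exposed count 3 < 4 excludes code b
  sel5 <- rank_high_dim(persons, codes, min_count = 4, k = 10)
  expect_false("b" %in% sel5$candidates$code)
  # k beyond the candidate count selects everything
  expect_equal(sort(rank_high_dim(persons, codes, min_count = 1,
                                  k = 50)$selected), c("a", "b", "c"))
  expect_error(rank_high_dim(persons, codes, k = 0), "positive")
})

test_that("selection is invariant to row order, with lexicographic ties", {
  coh <- small_cohort()
  coh2 <- assign_t0(coh, cohort_spec(), seed = 3)
  p <- coh2$persons[coh2$persons$group != "historical", ]
  sel1 <- rank_high_dim(p, coh2$codes, min_count = 10, k = 20)
  perm <- sample(nrow(p))
  sel2 <- rank_high_dim(p[perm, ], coh2$codes, min_count = 10, k = 20)
  expect_identical(sel1$selected, sel2$selected)
  # no silent drops when thresholds are off
  sel_all <- rank_high_dim(p, coh2$codes, min_count = 0, k = .Machine$integer.max)
  in_window <- local({
    idx <- match(coh2$codes$person_id, p$person_id)
    ok <- !is.na(idx)
    t0 <- p$t0[idx[ok]]
    w <- coh2$codes$date[ok] >= t0 - 365 & coh2$codes$date[ok] < t0
    unique(coh2$codes$code[ok][w])
  })
  expect_setequal(sel_all$candidates$code, in_window)
})

test_that("design matrix has the hand-counted structure", {
  t0 <- as.Date("2020-06-01")
  persons <- data.frame(
    person_id = 1:12, group = rep(c("exposed", "contemporary"), 6), t0 = t0,
    age = c(41, 52, 63, 44, 55, 66, 47, 58, 69, 50, 61, 72),
    sex = rep(c("male", "female"), 6),
    diabetes = rep(c(0, 1), each = 6),
    bmi = c(NA, 22, 24, 26, 28, 30, 32, 34, NA, 38, 40, 42))
  dm <- build_design_matrix(persons, c("age", "sex", "diabetes", "bmi"),
                            n_knots = 4)
  # age: 3 spline cols; sex: 1 indicator; diabetes: 1 flag; bmi: 3 spline
  expect_equal(ncol(dm$x), 8L)
  expect_false(anyNA(dm$x))
  expect_setequal(unique(dm$meta$type), c("spline", "indicator", "flag"))
  # two-level factor gets a single reference-coded column
  expect_equal(sum(dm$meta$source == "sex"), 1L)
})

test_that("selected codes enter the design matrix as 0/1 columns", {
  lm <- small_landmarked()
  pe <- lm$persons[lm$persons$group == "exposed", ][1:250, ]
  pc <- lm$persons[lm$persons$group == "contemporary", ][1:250, ]
  p <- rbind(pe, pc)
  sel <- rank_high_dim(p, lm$codes, min_count = 5, k = 5)
  dm <- build_design_matrix(p, c("age", "sex"), selection = sel,
                            codes = lm$codes)
  code_cols <- dm$meta$column[dm$meta$type == "code"]
  expect_equal(length(code_cols), length(sel$selected))
  expect_true(all(dm$x[, code_cols] %in% c(0, 1)))
})
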