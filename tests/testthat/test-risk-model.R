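test_that("intercept-only fit reproduces the closed-form log-odds", {
  y <- c(rep(1L, 17), rep(0L, 83))
  d <- design_from_counts(matrix(numeric(0), 100, 0), y)
  f <- fit_logistic(d)
  expect_equal(unname(f$coefficients["intercept"]), log(0.17 / 0.83), tolerance = 1e-8)
  expect_equal(predict_proba(f, d), rep(0.17, 100), tolerance = 1e-8)
  expect_equal(nrow(effects_table(f)), 0L)
})

test_that("a saturated 2x2 model matches the cross-product ratio and hand CI", {
  x <- c(rep(1, 15), rep(0, 60))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 20), rep(0, 40))
  d <- design_from_counts(matrix(x, dimnames = list(NULL, "exposure")), y)
  e <- effects_table(fit_logistic(d))
  se <- sqrt(1 / 10 + 1 / 5 + 1 / 20 + 1 / 40)
  expect_equal(e$or, 4.0, tolerance = 1e-6)
  expect_equal(e$ci_low, exp(log(4) - qnorm(0.975) * se), tolerance = 1e-6)
  expect_equal(e$ci_high, exp(log(4) + qnorm(0.975) * se), tolerance = 1e-6)
})

test_that("coefficients agree with a generic likelihood maximizer on small designs", {
  set.seed(17)
  for (i in 1:5) {
    n <- sample(60:200, 1)
    p <- sample(1:3, 1)
    X <- matrix(rpois(n * p, 1.2), n, p, dimnames = list(NULL, paste0("c", 1:p)))
    lp <- -1 + X %*% runif(p, -0.5, 0.5)
    y <- rbinom(n, 1, plogis(lp))
    if (length(unique(y)) < 2) next
    d <- design_from_counts(X, y)
    f <- tryCatch(fit_logistic(d), error = function(e) NULL)
    if (is.null(f) || f$separation_detected) next
    XX <- cbind(X, 1)
    nll <- function(b) -sum(dbinom(y, 1, plogis(XX %*% b), log = TRUE))
    ngr <- function(b) -as.numeric(t(XX) %*% (y - plogis(XX %*% b)))
    op <- optim(rep(0, p + 1), nll, gr = ngr, method = "BFGS",
                control = list(maxit = 2000, reltol = 1e-15))
    expect_equal(unname(f$coefficients), op$par, tolerance = 1e-6)
  }
})

test_that("row permutation and duplicated class-balanced rows leave the MLE finite", {
  set.seed(23)
  X <- matrix(rpois(80, 1), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(40, 1, plogis(-0.5 + 0.3 * X[, 1]))
  y[1:2] <- c(0L, 1L)
  d <- design_from_counts(X, y)
  f1 <- fit_logistic(d)
  perm <- sample(40)
  f2 <- fit_logistic(design_from_counts(X[perm, ], y[perm]))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  # append one row of each class with identical features
  X3 <- rbind(X, X[1, ], X[1, ])
  y3 <- c(y, 0L, 1L)
  f3 <- fit_logistic(design_from_counts(X3, y3))
  expect_true(all(is.finite(f3$coefficients)))
})

test_that("perfect separation is flagged and effect tables refuse it", {
  x <- c(-2, -1.5, -1, 1, 1.5, 2)
  y <- c(0, 0, 0, 1, 1, 1)
  d <- design_from_counts(matrix(x, dimnames = list(NULL, "x")), y)
  f <- fit_logistic(d)
  expect_true(f$separation_detected)
  expect_error(effects_table(f), "separation")
})

test_that("significance flag is equivalent to the CI excluding 1", {
  set.seed(41)
  for (i in 1:10) {
    n <- 500
    X <- matrix(rpois(2 * n, 1.5), n, 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(n, 1, plogis(-1.5 + 0.25 * X[, 1]))
    if (length(unique(y)) < 2) next
    e <- effects_table(fit_logistic(design_from_counts(X, y)))
    expect_identical(e$significant, e$ci_low > 1 | e$ci_high < 1)
    expect_true(all(e$ci_low <= e$or & e$or <= e$ci_high))
    expect_true(all(e$or > 0))
  }
})

test_that("predicted probabilities are monotone in a positive coefficient and checked", {
  X <- matrix(0:10, dimnames = list(NULL, "a"))
  y <- c(0, 0, 0, 0, 1, 0, 1, 1, 0, 1, 1)
  d <- design_from_counts(X, y)
  f <- fit_logistic(d)
  ph <- predict_proba(f, d)
  expect_true(all(diff(ph) > 0))
  expect_true(all(ph > 0 & ph < 1))
  # hand-computed sigmoid on three rows
  b <- f$coefficients
  expect_equal(ph[c(1, 5, 11)],
               plogis(b["intercept"] + b["a"] * c(0, 4, 10)),
               ignore_attr = TRUE)
  bad <- d$x[, c(2, 1)]
  expect_error(predict_proba(f, bad), "column mismatch")
})

test_that("Hosmer-Lemeshow matches the reference tail probability and binning rules", {
  expect_equal(round(hl_pvalue(11.21, 8), 2), 0.19)

  set.seed(57)
  X <- matrix(rpois(4000, 1.5), 2000, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(2000, 1, plogis(-1.6 + 0.3 * X[, 1] - 0.2 * X[, 2]))
  d <- design_from_counts(X, y)
  f <- fit_logistic(d)
  hl <- hosmer_lemeshow(f, d)
  expect_true(hl$df >= 1 && hl$df <= 8)
  expect_true(hl$p_value >= 0 && hl$p_value <= 1)
  expect_equal(sum(hl$table$n), 2000L)
  # near-equal-size bins (ties kept together can distort sizes slightly)
  expect_true(max(hl$table$n) <= 2 * min(hl$table$n) + max(table(round(predict_proba(f, d), 12))))

  expect_error(hosmer_lemeshow(f, design_from_counts(X[1:5, ], c(0, 1, 0, 1, 0)),
                               groups = 10), "at least 10")
})

test_that("Hosmer-Lemeshow rejects at roughly the nominal rate under the true model", {
  set.seed(71)
  reps <- 150
  rej <- 0
  for (r in seq_len(reps)) {
    X <- matrix(rpois(3000, 1.2), 1500, 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(1500, 1, plogis(-1.5 + 0.3 * X[, 1] - 0.15 * X[, 2]))
    if (length(unique(y)) < 2) next
    d <- design_from_counts(X, y)
    f <- fit_logistic(d)
    hl <- tryCatch(hosmer_lemeshow(f, d), error = function(e) NULL)
    if (!is.null(hl) && hl$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.005)
  expect_lt(rej / reps, 0.13)
})

test_that("univariable screening fits one model per category", {
  set.seed(83)
  X <- matrix(rpois(900, 1.5), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(300, 1, plogis(-1 + 0.4 * X[, 1]))
  d <- design_from_counts(X, y)
  u <- fit_univariable(d)
  expect_equal(u$category_id, c("a", "b", "c"))
  # each row equals its own single-predictor fit
  d1 <- design_from_counts(X[, "b", drop = FALSE], y)
  expect_equal(u$or[2], effects_table(fit_logistic(d1))$or, tolerance = 1e-10)
})
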