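test_that("F-measures reproduce the reference worked example", {
  expect_equal(round(100 * fbeta_score(0.728, 0.484, beta = 1), 1), 58.1)
  expect_equal(round(100 * fbeta_score(0.728, 0.484, beta = 2), 1), 51.9)
})

test_that("F-beta interpolates precision and recall and drifts toward recall", {
  # symmetry: P = R = x gives F_beta = x for any beta
  for (x in c(0.1, 0.5, 0.9)) {
    for (b in c(0.5, 1, 2, 4)) expect_equal(fbeta_score(x, x, b), x)
  }
  grid <- expand.grid(p = c(0.2, 0.5, 0.9), r = c(0.1, 0.4, 0.8))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; r <- grid$r[i]
    f1 <- fbeta_score(p, r, 1); f2 <- fbeta_score(p, r, 2); f4 <- fbeta_score(p, r, 4)
    expect_true(f1 >= min(p, r) - 1e-12 && f1 <= max(p, r) + 1e-12)
    # larger beta moves F toward recall
    if (r < p) expect_true(f4 <= f2 && f2 <= f1)
    if (r > p) expect_true(f4 >= f2 && f2 >= f1)
  }
  expect_warning(fbeta_score(0, 0, 1), "both 0")
})

test_that("precision/recall handle counts and degenerate denominators", {
  y_true <- c(1, 1, 1, 0, 0, 0, 1, 0)
  y_pred <- c(1, 0, 1, 1, 0, 0, 0, 0)
  m <- precision_recall_fbeta(y_true, y_pred, beta = 1)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 4)
  expect_equal(m$f_beta, 2 * (2 / 3) * (1 / 2) / (2 / 3 + 1 / 2))
  expect_error(precision_recall_fbeta(c(1, 0), c(1, 0, 1)), "length mismatch")
  w <- capture_warnings(precision_recall_fbeta(c(1, 0), c(0, 0)))
  expect_match(w, "no positive predictions", all = FALSE)
})

test_that("rank-based AUC equals trapezoidal ROC integration and honors ties", {
  # perfect ordering and all-tied scores
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both outcome classes")

  trapezoid_auc <- function(y, s) {
    th <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
    tpr <- vapply(th, function(t) mean(s[y == 1] >= t), 0)
    fpr <- vapply(th, function(t) mean(s[y == 0] >= t), 0)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  set.seed(202)
  for (i in 1:60) {
    n <- sample(10:80, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(roc_auc(y, s), trapezoid_auc(y, s), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(303)
  y <- rbinom(200, 1, 0.3)
  y[1:2] <- c(0, 1)
  s <- rnorm(200)
  a <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), a, tolerance = 1e-12)
  expect_equal(roc_auc(y, plogis(3 * s + 1)), a, tolerance = 1e-12)
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(404)
  y <- rbinom(300, 1, 0.25); y[1:2] <- c(0, 1)
  s <- round(rnorm(300), 1)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
})

test_that("Cohen's kappa matches hand computation and error contracts", {
  r1 <- c(rep(1, 40), rep(1, 10), rep(0, 10), rep(0, 40))
  r2 <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  expect_equal(cohen_kappa(r1, r2), 0.6)  # p_o = 0.8, p_e = 0.5
  # perfect agreement with mixed marginals
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  # both raters constant and identical: undefined
  expect_error(cohen_kappa(rep(1, 5), rep(1, 5)), "undefined")
})

test_that("independent raters give kappa near zero", {
  set.seed(505)
  r1 <- rbinom(20000, 1, 0.4)
  r2 <- rbinom(20000, 1, 0.6)
  expect_lt(abs(cohen_kappa(r1, r2)), 0.03)
})

test_that("multi-rater reductions: mean pairwise Cohen and Fleiss", {
  set.seed(606)
  base <- rbinom(300, 1, 0.35)
  flip <- function(x, p) ifelse(runif(length(x)) < p, 1 - x, x)
  m <- cbind(flip(base, 0.1), flip(base, 0.15), flip(base, 0.2))
  ck <- cohen_kappa(m)
  expect_identical(ck$method, "mean pairwise Cohen's kappa")
  expect_length(ck$pairwise, 3L)
  expect_equal(ck$kappa, mean(ck$pairwise))
  fk <- fleiss_kappa(m)
  expect_true(fk > 0.4 && fk < 1)
  expect_equal(fleiss_kappa(cbind(base, base, base)), 1)
})

test_that("holdout splits are deterministic, stratified and sized correctly", {
  y <- rep(c(0, 1), c(80, 20))
  s1 <- split_holdout(y, 0.2, seed = 9)
  s2 <- split_holdout(y, 0.2, seed = 9)
  expect_identical(s1, s2)
  expect_length(s1$test, 20L)
  expect_equal(mean(y[s1$test]), mean(y), tolerance = 0.051)
  expect_setequal(c(s1$train, s1$test), seq_along(y))
  expect_error(split_holdout(rep(0:1, 2), 0.2), "at least 10")
})

test_that("holdout evaluation reports coherent metrics on a learnable corpus", {
  set.seed(808)
  n <- 4000
  X <- matrix(rpois(2 * n, 1.5), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(-2 + 0.9 * X[, 1]))
  d <- design_from_counts(X, y)
  ev <- evaluate_holdout(d, test_fraction = 0.25, seed = 3)
  expect_equal(ev$n_test, round(0.25 * sum(y == 0)) + round(0.25 * sum(y == 1)))
  expect_true(ev$roc_auc > 0.6)
  expect_true(all(unlist(ev[c("precision", "recall", "f1", "f2")]) >= 0))
  expect_true(all(unlist(ev[c("precision", "recall", "f1", "f2")]) <= 1))
  # F arithmetic consistent with reported precision/recall
  expect_equal(ev$f1, fbeta_score(ev$precision, ev$recall, 1))
  expect_equal(ev$f2, fbeta_score(ev$precision, ev$recall, 2))
})
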