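# Held-out predictive evaluation and agreement statistics.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Train/test split indices
#'
#' Deterministic given `seed`. With `stratify_by_outcome = TRUE` (default) the
#' split samples within each outcome class, preserving prevalence up to
#' rounding (one session per class).
#'
#' @param y Binary outcome vector (length at least 10).
#' @param test_fraction Fraction of sessions held out, in (0, 1).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param stratify_by_outcome Stratify the split by outcome (default `TRUE`).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_holdout <- function(y, test_fraction = 0.2, seed = NULL,
                          stratify_by_outcome = TRUE) {
  y <- as.integer(y)
  n <- length(y)
  if (n < 10) stop("need at least 10 sessions to split")
  if (test_fraction <= 0 || test_fraction >= 1) stop("test_fraction must be in (0, 1)")
  with_seed(seed, {
    if (stratify_by_outcome) {
      test <- unlist(lapply(unique(y), function(cls) {
        idx <- which(y == cls)
        sample(idx, round(test_fraction * length(idx)))
      }))
      test <- sort(test)
    } else {
      test <- sort(sample(n, round(test_fraction * n)))
      if (length(unique(y[test])) < 2L) {
        warning("non-stratified test set contains a single outcome class")
      }
    }
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Precision, recall and F-beta from binary predictions
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F_beta = (1+beta^2) P R / (beta^2 P + R)`. A zero denominator yields 0
#' with a warning.
#'
#' @param y_true Binary truth vector.
#' @param y_pred Binary prediction vector, same length.
#' @param beta F-measure weight (1 = F1; 2 weights recall higher).
#' @return List with `precision`, `recall`, `f_beta`, `beta`.
#' @export
precision_recall_fbeta <- function(y_true, y_pred, beta = 1) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch between y_true and y_pred")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  precision <- if (tp + fp == 0) {
    warning("no positive predictions; precision set to 0"); 0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) {
    warning("no positive truths; recall set to 0"); 0
  } else tp / (tp + fn)
  f <- fbeta_score(precision, recall, beta)
  list(precision = precision, recall = recall, f_beta = f, beta = beta)
}

#' F-beta score from precision and recall
#'
#' @param precision,recall Values in \[0, 1\].
#' @param beta F-measure weight.
#' @return The weighted harmonic mean `(1+beta^2) P R / (beta^2 P + R)`; 0
#'   (with a warning) when both inputs are 0.
#' @export
fbeta_score <- function(precision, recall, beta = 1) {
  denom <- beta^2 * precision + recall
  if (denom == 0) {
    warning("precision and recall both 0; F set to 0")
    return(0)
  }
  (1 + beta^2) * precision * recall / denom
}

#' Rank-based ROC-AUC
#'
#' Mann-Whitney AUC with midranks for tied scores; equals the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param y_true Binary truth vector (both classes present).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) stop("length mismatch between y_true and scores")
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)  # midranks for ties
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with expected
#' agreement from the rater marginals. With more than two raters the mean of
#' all pairwise kappas is returned (flagged in the result); see
#' [fleiss_kappa()] for the multi-rater alternative.
#'
#' @param ratings Matrix or data frame, one row per item, one column per
#'   rater; or a vector for rater 1 with `ratings2` for rater 2.
#' @param ratings2 Optional second rater vector.
#' @return For two raters, the kappa value; for more, a list with `kappa`
#'   (mean pairwise), `pairwise` and `method = "mean pairwise Cohen's kappa"`.
#' @export
cohen_kappa <- function(ratings, ratings2 = NULL) {
  if (!is.null(ratings2)) ratings <- cbind(ratings, ratings2)
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2) stop("need at least two raters")
  if (nrow(ratings) < 1) stop("need at least one rated item")
  if (ncol(ratings) == 2) return(kappa_pair(ratings[, 1], ratings[, 2]))
  pairs <- utils::combn(ncol(ratings), 2)
  pk <- apply(pairs, 2, function(ij) kappa_pair(ratings[, ij[1]], ratings[, ij[2]]))
  list(kappa = mean(pk), pairwise = pk, method = "mean pairwise Cohen's kappa")
}

kappa_pair <- function(a, b) {
  stopifnot(length(a) == length(b))
  lev <- sort(unique(c(a, b)))
  ta <- factor(a, levels = lev); tb <- factor(b, levels = lev)
  tab <- table(ta, tb)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps^0.5) {
    stop("expected agreement is 1 (constant identical marginals); kappa undefined")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Fleiss' kappa for multiple raters
#'
#' @param ratings Matrix/data frame of labels, one row per item, one column
#'   per rater (every item rated by every rater).
#' @return Fleiss' kappa value.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); m <- ncol(ratings)
  if (m < 2) stop("need at least two raters")
  lev <- sort(unique(as.vector(ratings)))
  nij <- t(apply(ratings, 1, function(r) tabulate(factor(r, levels = lev),
                                                  nbins = length(lev))))
  if (length(lev) == 1L) stop("all ratings identical; kappa undefined")
  p_i <- (rowSums(nij^2) - m) / (m * (m - 1))
  p_bar <- mean(p_i)
  pj <- colSums(nij) / (n * m)
  p_e <- sum(pj^2)
  if (1 - p_e < .Machine$double.eps^0.5) stop("expected agreement is 1; kappa undefined")
  (p_bar - p_e) / (1 - p_e)
}

#' Held-out evaluation of the logistic model
#'
#' Splits the design (stratified by outcome), fits on the training rows,
#' scores the test rows, and reports threshold metrics plus ROC-AUC.
#'
#' @param design An `srf_design` for the full sample.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param seed Optional seed for the split.
#' @param threshold Probability threshold for the positive call (default 0.5;
#'   the choice is reported alongside the metrics).
#' @return List with `precision`, `recall`, `f1`, `f2`, `roc_auc`,
#'   `threshold`, `n_train`, `n_test`, and the fitted `srf_logit`.
#' @export
evaluate_holdout <- function(design, test_fraction = 0.2, seed = NULL,
                             threshold = 0.5) {
  stopifnot(inherits(design, "srf_design"))
  sp <- split_holdout(design$y, test_fraction, seed = seed)
  sub <- function(idx) design_from_counts(
    design$x[idx, setdiff(colnames(design$x), "intercept"), drop = FALSE],
    design$y[idx], session_id = design$session_id[idx],
    stratum = design$stratum, fraction = design$fraction)
  fit <- fit_logistic(sub(sp$train))
  test <- sub(sp$test)
  phat <- predict_proba(fit, test)
  pred <- as.integer(phat >= threshold)
  m1 <- precision_recall_fbeta(test$y, pred, beta = 1)
  f2 <- fbeta_score(m1$precision, m1$recall, beta = 2)
  list(precision = m1$precision, recall = m1$recall, f1 = m1$f_beta, f2 = f2,
       roc_auc = roc_auc(test$y, phat), threshold = threshold,
       n_train = length(sp$train), n_test = length(sp$test), fit = fit)
}
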