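# Logistic modelling layer: maximum-likelihood fits (IRLS via stats::glm.fit),
# odds-ratio effect tables with Wald 95% CIs, predicted probabilities, and
# Hosmer-Lemeshow calibration.

#' Fit an intercept-included logistic regression
#'
#' Maximum-likelihood estimation by iteratively reweighted least squares
#' (delegated to [stats::glm.fit()]), with convergence declared when the
#' relative change in deviance falls below `1e-10` (at most 100 iterations).
#' Quasi-complete separation - diverging coefficients with fitted
#' probabilities pinned to 0/1 - is detected and flagged; a separated fit
#' carries no usable covariance and [effects_table()] refuses it.
#'
#' @param design An `srf_design` from [build_design()] or
#'   [design_from_counts()].
#' @return An object of class `srf_logit`: coefficients (log-odds scale),
#'   covariance matrix (inverse observed information), log-likelihood,
#'   convergence and separation flags, iteration count.
#' @export
fit_logistic <- function(design) {
  stopifnot(inherits(design, "srf_design"))
  x <- design$x
  y <- design$y
  # constant non-intercept columns make the model unidentifiable
  nonint <- setdiff(colnames(x), "intercept")
  csd <- apply(x[, nonint, drop = FALSE], 2, sd)
  if (any(csd == 0)) {
    stop("constant non-intercept column(s): ",
         paste(nonint[csd == 0], collapse = ", "))
  }
  boundary_warn <- FALSE
  fit <- withCallingHandlers(
    glm.fit(x, y, family = binomial(),
            control = glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        boundary_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (fit$rank < ncol(x)) {
    stop("design matrix is rank deficient (aliased columns) in stratum '",
         design$stratum, "'")
  }
  beta <- fit$coefficients
  p <- length(beta)
  qrr <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  covmat <- chol2inv(qrr)
  dimnames(covmat) <- list(names(beta), names(beta))
  mu <- fit$fitted.values
  loglik <- sum(dbinom(y, 1, mu, log = TRUE))
  slope <- beta[setdiff(names(beta), "intercept")]
  separated <- length(slope) > 0 &&
    (boundary_warn || any(mu < 1e-10) || any(mu > 1 - 1e-10)) &&
    (max(abs(slope)) > 8 || max(sqrt(diag(covmat))) > 20)
  if (!fit$converged && !separated) {
    stop("IRLS did not converge in 100 iterations (stratum '", design$stratum, "')")
  }
  structure(list(coefficients = beta, vcov = covmat, loglik = loglik,
                 converged = fit$converged, n_iterations = fit$iter,
                 separation_detected = separated,
                 n = length(y), prevalence = mean(y),
                 stratum = design$stratum, fraction = design$fraction,
                 column_names = colnames(x)),
            class = "srf_logit")
}

#' @export
print.srf_logit <- function(x, ...) {
  cat("<srf_logit> stratum=", x$stratum, ", n=", x$n,
      ", loglik=", round(x$loglik, 2),
      ", converged=", x$converged,
      if (x$separation_detected) ", SEPARATION DETECTED", "\n", sep = "")
  invisible(x)
}

#' Odds-ratio effect table from a logistic fit
#'
#' For every non-intercept column: `OR = exp(beta)`, a Wald confidence
#' interval `exp(beta +/- z * SE)` on the log-odds scale, and a two-sided Wald
#' z-test p-value. The significance flag is `p < alpha`, which for Wald
#' inference is equivalent to the CI excluding 1.0.
#'
#' @param fit An `srf_logit`.
#' @param alpha Significance level (default 0.05; CI level is `1 - alpha`).
#' @param p_adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"none"`, matching per-predictor reporting; `"BH"` available).
#' @return A tibble: `stratum`, `fraction`, `category_id`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `significant`.
#' @export
effects_table <- function(fit, alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(fit, "srf_logit"))
  if (fit$separation_detected) {
    stop("separation detected in stratum '", fit$stratum,
         "': odds ratios and Wald CIs are not identified")
  }
  keep <- setdiff(names(fit$coefficients), "intercept")
  beta <- unname(fit$coefficients[keep])
  se <- unname(sqrt(diag(fit$vcov))[keep])
  z <- qnorm(1 - alpha / 2)
  p <- 2 * pnorm(-abs(beta / se))
  p_adj <- p.adjust(p, method = p_adjust)
  tibble::tibble(
    stratum = fit$stratum,
    fraction = fit$fraction,
    category_id = keep,
    or = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p_value = p_adj,
    significant = p_adj < alpha
  )
}

#' Predicted SR probabilities
#'
#' `plogis(x %*% beta)` for a fitted model; columns of the new design must
#' match the fit's columns exactly.
#'
#' @param fit An `srf_logit`.
#' @param newdata An `srf_design` or a numeric matrix with the fit's columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(fit, newdata) {
  stopifnot(inherits(fit, "srf_logit"))
  x <- if (inherits(newdata, "srf_design")) newdata$x else as.matrix(newdata)
  if (!identical(colnames(x), fit$column_names)) {
    stop("column mismatch: fit has [", paste(fit$column_names, collapse = ", "),
         "], newdata has [", paste(colnames(x), collapse = ", "), "]")
  }
  as.numeric(plogis(x %*% fit$coefficients))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Rows are sorted by predicted probability and split into `groups`
#' near-equal-size bins (tied predictions stay together). The statistic sums
#' `(observed - expected)^2 / expected` over bins and both outcome classes;
#' degrees of freedom are `bins - 2` and the p-value is the upper chi-squared
#' tail.
#'
#' @param fit An `srf_logit`.
#' @param design The `srf_design` to evaluate calibration on.
#' @param groups Number of probability bins (default 10, i.e. deciles).
#' @return List of class `srf_hl`: `chi2`, `df`, `p_value`, and a per-bin
#'   observed/expected table.
#' @export
hosmer_lemeshow <- function(fit, design, groups = 10) {
  stopifnot(inherits(design, "srf_design"), groups >= 3)
  y <- design$y
  if (length(y) < groups) {
    stop("need at least ", groups, " observations for ", groups, " bins")
  }
  phat <- predict_proba(fit, design)
  br <- unique(quantile(phat, probs = seq(0, 1, length.out = groups + 1),
                        names = FALSE))
  if (length(br) < 3) stop("predicted probabilities too tied for ", groups, " bins")
  bin <- cut(phat, breaks = br, include.lowest = TRUE)
  o1 <- tapply(y, bin, sum)
  e1 <- tapply(phat, bin, sum)
  n_g <- tapply(y, bin, length)
  keep <- !is.na(n_g)
  o1 <- o1[keep]; e1 <- e1[keep]; n_g <- n_g[keep]
  o0 <- n_g - o1
  e0 <- n_g - e1
  if (any(e1 <= 0) || any(e0 <= 0)) {
    stop("a bin has expected count 0; use fewer groups")
  }
  chi2 <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
  df <- length(n_g) - 2
  if (df < 1) stop("too few distinct bins; use more data or fewer groups")
  structure(list(chi2 = chi2, df = df,
                 p_value = hl_pvalue(chi2, df),
                 table = tibble::tibble(bin = names(n_g), n = as.integer(n_g),
                                        observed = as.numeric(o1),
                                        expected = as.numeric(e1))),
            class = "srf_hl")
}

#' Hosmer-Lemeshow tail probability
#'
#' Upper-tail chi-squared probability of an HL statistic, e.g. a reported
#' `chi2(8) = 11.21` gives `p = 0.19`.
#'
#' @param chi2 Test statistic.
#' @param df Degrees of freedom (`bins - 2`).
#' @return The p-value.
#' @export
hl_pvalue <- function(chi2, df) {
  stopifnot(chi2 >= 0, df >= 1)
  pchisq(chi2, df, lower.tail = FALSE)
}

#' @export
print.srf_hl <- function(x, ...) {
  cat("Hosmer-Lemeshow: chi2(", x$df, ") = ", round(x$chi2, 2),
      ", p = ", round(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Univariable effect screen
#'
#' Fits one logistic model per category (intercept + that category alone) and
#' stacks the effect rows; a companion to the default multivariable model.
#'
#' @inheritParams effects_table
#' @param design An `srf_design`.
#' @return A tibble in [effects_table()] format.
#' @export
fit_univariable <- function(design, alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(design, "srf_design"))
  cats <- setdiff(colnames(design$x), "intercept")
  rows <- lapply(cats, function(cc) {
    d1 <- design_from_counts(design$x[, cc, drop = FALSE], design$y,
                             session_id = design$session_id,
                             stratum = design$stratum, fraction = design$fraction)
    effects_table(fit_logistic(d1), alpha = alpha, p_adjust = "none")
  })
  out <- do.call(rbind, rows)
  out$p_value <- p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  out
}
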