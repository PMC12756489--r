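# Stratified fits (gender; age) and temporal trajectories across the five
# chat-progress fractions.

strata_levels <- function(stratification) {
  switch(stratification,
         none   = list(var = NULL, levels = "all"),
         gender = list(var = "gender", levels = c("all", "female", "male")),
         age    = list(var = "age_group", levels = c("10-17", "18-20", "21-40", "41+")),
         stop("stratification must be one of 'none', 'gender', 'age'"))
}

design_for_stratum <- function(features, var, level) {
  if (is.null(var) || level == "all") {
    build_design(features)
  } else {
    build_design(features, stratum_var = var, stratum_value = level)
  }
}

#' Fit one logistic model per stratum
#'
#' `stratification = "gender"` fits the full-sample "all" model plus
#' female/male models; `"age"` fits one model per age group; `"none"` fits the
#' single "all" model. Sessions with unknown demographics stay in the "all"
#' model but are dropped from the corresponding strata. Per-stratum sample
#' size and SR prevalence are reported alongside the effects (sample
#' accounting discipline).
#'
#' @param features An `srf_features` tibble ([featurize_sessions()] or
#'   [ground_truth_features()]).
#' @param stratification `"none"`, `"gender"` or `"age"`.
#' @param alpha Significance level for effect tables.
#' @param p_adjust Multiple-testing correction (default `"none"`).
#' @return An object of class `srf_strata`: list with `stratification`,
#'   `fits` (named list of `srf_logit`), `effects` (stacked effect tibble) and
#'   `accounting` (per-stratum n and prevalence).
#' @export
fit_by_stratum <- function(features, stratification = c("gender", "age", "none"),
                           alpha = 0.05, p_adjust = "none") {
  stratification <- match.arg(stratification)
  sl <- strata_levels(stratification)
  fits <- list()
  effects <- list()
  accounting <- list()
  for (lev in sl$levels) {
    design <- tryCatch(design_for_stratum(features, sl$var, lev),
                       error = function(e) stop("stratum '", lev, "': ",
                                                conditionMessage(e), call. = FALSE))
    fit <- fit_logistic(design)
    fits[[lev]] <- fit
    effects[[lev]] <- effects_table(fit, alpha = alpha, p_adjust = p_adjust)
    accounting[[lev]] <- tibble::tibble(stratum = lev, n = fit$n,
                                        sr_cases = sum(design$y),
                                        prevalence = fit$prevalence)
  }
  effects <- do.call(rbind, effects)
  rownames(effects) <- NULL
  structure(list(stratification = stratification,
                 fits = fits,
                 effects = effects,
                 accounting = do.call(rbind, accounting)),
            class = "srf_strata")
}

#' @export
print.srf_strata <- function(x, ...) {
  cat("<srf_strata> stratification=", x$stratification, "\n", sep = "")
  print(x$accounting)
  invisible(x)
}

#' Temporal trajectories of predictor effects across chat fractions
#'
#' For each progress fraction, features are rebuilt on the sliced prefixes and
#' the full multivariable model is refit per stratum (repeated cross-sectional
#' design); the fraction-1.0 point equals the static stratified fit exactly.
#'
#' @param x Either a list of `chat_session` objects (then `lexicon` is
#'   required and features are computed per fraction) or a named list of
#'   `srf_features` tibbles keyed by fraction (names like `"0.2"`), e.g. from
#'   the generator's count-level path.
#' @param lexicon A compiled `srf_lexicon` (only when `x` is a session list).
#' @param stratification `"none"`, `"gender"` or `"age"`.
#' @param fractions Progress fractions (default the five canonical stages).
#' @param alpha Significance level.
#' @param ... Passed to [featurize_sessions()].
#' @return A tibble: `stratum`, `category_id`, `fraction`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `significant` - one row per (stratum, category,
#'   fraction), five points per trajectory.
#' @export
temporal_trajectories <- function(x, lexicon = NULL,
                                  stratification = c("gender", "age", "none"),
                                  fractions = srf_fractions, alpha = 0.05, ...) {
  stratification <- match.arg(stratification)
  if (is.list(x) && length(x) && inherits(x[[1]], "chat_session")) {
    stopifnot(!is.null(lexicon))
    feats <- lapply(fractions, function(f) featurize_sessions(x, lexicon, fraction = f, ...))
    names(feats) <- format(fractions)
  } else {
    feats <- x
    if (is.null(names(feats))) stop("feature list must be named by fraction")
    fractions <- as.numeric(names(feats))
  }
  rows <- lapply(seq_along(feats), function(i) {
    st <- tryCatch(fit_by_stratum(feats[[i]], stratification, alpha = alpha),
                   error = function(e) stop("fraction ", fractions[i], ": ",
                                            conditionMessage(e), call. = FALSE))
    eff <- st$effects
    eff$fraction <- fractions[i]
    eff
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$stratum, out$category_id, out$fraction),
             c("stratum", "category_id", "fraction", "or", "ci_low", "ci_high",
               "p_value", "significant")]
  rownames(out) <- NULL
  out
}

#' Wald contrast of one coefficient across two independent strata
#'
#' Utility extension (no cross-stratum tests are part of the core reporting):
#' z-test of `beta_1 - beta_2` using the two fits' standard errors, valid
#' because strata are disjoint samples.
#'
#' @param fit1,fit2 `srf_logit` fits from disjoint strata.
#' @param category_id The coefficient to compare.
#' @return List with `delta_log_or`, `se`, `z`, `p_value`.
#' @export
wald_contrast <- function(fit1, fit2, category_id) {
  stopifnot(inherits(fit1, "srf_logit"), inherits(fit2, "srf_logit"))
  b1 <- fit1$coefficients[category_id]; b2 <- fit2$coefficients[category_id]
  v1 <- diag(fit1$vcov)[category_id];   v2 <- diag(fit2$vcov)[category_id]
  if (anyNA(c(b1, b2))) stop("category '", category_id, "' not in both fits")
  z <- (b1 - b2) / sqrt(v1 + v2)
  list(delta_log_or = unname(b1 - b2), se = unname(sqrt(v1 + v2)),
       z = unname(z), p_value = unname(2 * pnorm(-abs(z))))
}
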