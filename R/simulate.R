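# Synthetic chat-corpus generator: known group structure, planted lexicon
# phrase counts with stage-dependent Poisson intensities, and SR labels drawn
# from a known logistic model on the total counts. Stands in for the
# confidential helpline data and makes exact end-to-end recovery testable.
#
# Construction guarantees:
#   * filler vocabulary is token-disjoint from every lexicon phrase, so filler
#     text can never match;
#   * planted phrases are always separated by at least one filler token
#     (within and across messages), so no spurious cross-phrase matches arise;
#   * every help-seeker message is padded to the same character length, so the
#     five per-session stages have identical help-seeker character counts and
#     character-fraction slicing at f = s/5 captures exactly stages 1..s.

#' Reference subgroup table of a large crisis-helpline chat corpus
#'
#' Subgroup sizes and suicide-risk case counts of the Hebrew crisis-helpline
#' corpus (17,564 sessions, 2017-2021) that the default generator emulates.
#' Prevalence is recomputed as `n_sr / n_total`.
#'
#' @return A tibble: `dimension` (all/gender/age), `subgroup`, `n_total`,
#'   `n_sr`, `prevalence`.
#' @export
crisis_sample_table <- function() {
  tab <- tibble::tibble(
    dimension = c("all", rep("gender", 3), rep("age", 5)),
    subgroup  = c("all", "female", "male", "unknown",
                  "10-17", "18-20", "21-40", "41+", "unknown"),
    n_total   = c(17564, 12074, 5343, 147, 4179, 3283, 8603, 1467, 32),
    n_sr      = c(3097, 2173, 908, 16, 627, 671, 1482, 314, 3)
  )
  tab$prevalence <- tab$n_sr / tab$n_total
  tab
}

#' Default filler vocabulary
#'
#' Pronounceable nonsense tokens, several per character length 1-10, sharing
#' no token with any phrase of the packaged toy lexicon. The length coverage
#' lets the generator pad messages to exact character targets.
#'
#' @return Character vector of filler tokens.
#' @export
default_filler_vocab <- function() {
  c("q", "z", "x",
    "zu", "qo", "xi",
    "zim", "vop", "kex",
    "quab", "zorp", "melk", "virn",
    "blorp", "frazz", "quimp", "zandl",
    "zumble", "plonka", "brimzo",
    "zorgleb", "quampix", "flumbar",
    "blenkarf", "zippalog", "vrumpelid",
    "zumbering", "quaboodle", "florpitan",
    "zorbulance", "flimmerzap", "quandelbro")
}

filler_by_length <- function(filler) {
  lens <- stringi::stri_length(filler)
  out <- lapply(1:10, function(L) filler[lens == L])
  if (any(!vapply(out, length, integer(1)))) {
    stop("filler vocabulary must contain tokens of every length 1..10 ",
         "(needed for exact-length message padding)")
  }
  out
}

lexicon_token_set <- function(lexicon) {
  unique(unlist(lapply(lexicon$categories, function(cc) {
    unlist(lapply(cc$phrases, phrase_tokens,
                  case_fold = isTRUE(lexicon$settings$case_fold)))
  })))
}

# A lexicon supports exact planting iff each phrase, standing alone, matches
# once in its own category and never in any other category.
validate_plantable <- function(lexicon, filler) {
  coll <- intersect(tolower(filler), lexicon_token_set(lexicon))
  if (length(coll)) {
    stop("filler/lexicon token collision: ", paste(coll, collapse = ", "))
  }
  ids <- lexicon_categories(lexicon)
  for (k in seq_along(ids)) {
    for (ph in lexicon$categories[[k]]$compiled) {
      counts <- count_matches(lexicon, ph$clean)
      expected <- setNames(rep(0L, length(ids)), ids)
      expected[ids[k]] <- 1L
      if (!identical(unname(counts[ids]), unname(expected))) {
        stop("phrase '", ph$raw, "' of category '", ids[k],
             "' is not uniquely plantable (matches: ",
             paste(names(counts)[counts > 0], collapse = ", "),
             "); adjust the lexicon for exact-recovery generation")
      }
    }
  }
  invisible(TRUE)
}

#' Construct a generator configuration
#'
#' @param n_sessions Number of sessions to generate.
#' @param cell_probs 3 x 5 matrix of joint (gender x age) cell probabilities
#'   (rows `female`/`male`/`unknown`, columns the four age groups plus
#'   `unknown`), summing to 1.
#' @param stage_rates K x 5 matrix of Poisson means: expected planted matches
#'   of category k in stage s of a chat. Row names are category ids.
#' @param true_beta K x 3 matrix of true log-odds-ratio coefficients per
#'   gender (columns `female`/`male`/`unknown`).
#' @param beta0 3 x 5 matrix of per-cell intercepts (see
#'   [calibrate_intercept()]), or `NULL` together with `cell_prevalence`.
#' @param cell_prevalence Optional 3 x 5 matrix of target SR prevalences,
#'   used by [default_config()] to calibrate `beta0`.
#' @param filler Filler vocabulary (token-disjoint from the lexicon; must
#'   cover token lengths 1-10).
#' @param messages_per_stage Help-seeker messages per stage (default 2).
#' @param message_chars Minimum cleaned character length of each help-seeker
#'   message (default 110; raised per session when planted content needs it).
#' @return A validated list of class `srf_gen_config`.
#' @export
generator_config <- function(n_sessions, cell_probs, stage_rates, true_beta,
                             beta0 = NULL, cell_prevalence = NULL,
                             filler = default_filler_vocab(),
                             messages_per_stage = 2, message_chars = 110) {
  stopifnot(n_sessions >= 1)
  cell_probs <- as.matrix(cell_probs)
  stopifnot(nrow(cell_probs) == 3, ncol(cell_probs) == 5,
            all(cell_probs >= 0), abs(sum(cell_probs) - 1) < 1e-8)
  dimnames(cell_probs) <- list(srf_genders, srf_age_groups)
  stage_rates <- as.matrix(stage_rates)
  stopifnot(ncol(stage_rates) == 5, all(stage_rates >= 0),
            !is.null(rownames(stage_rates)))
  true_beta <- as.matrix(true_beta)
  stopifnot(nrow(true_beta) == nrow(stage_rates), ncol(true_beta) == 3,
            all(is.finite(true_beta)))
  dimnames(true_beta) <- list(rownames(stage_rates), srf_genders)
  if (is.null(beta0) && is.null(cell_prevalence)) {
    stop("provide beta0 or cell_prevalence")
  }
  if (!is.null(beta0)) {
    beta0 <- as.matrix(beta0)
    stopifnot(nrow(beta0) == 3, ncol(beta0) == 5, all(is.finite(beta0)))
    dimnames(beta0) <- list(srf_genders, srf_age_groups)
  }
  if (!is.null(cell_prevalence)) {
    cell_prevalence <- as.matrix(cell_prevalence)
    stopifnot(nrow(cell_prevalence) == 3, ncol(cell_prevalence) == 5,
              all(cell_prevalence > 0), all(cell_prevalence < 1))
    dimnames(cell_prevalence) <- list(srf_genders, srf_age_groups)
  }
  stopifnot(messages_per_stage >= 1, message_chars >= 30)
  structure(list(n_sessions = as.integer(n_sessions), cell_probs = cell_probs,
                 stage_rates = stage_rates, true_beta = true_beta,
                 beta0 = beta0, cell_prevalence = cell_prevalence,
                 categories = rownames(stage_rates), filler = filler,
                 messages_per_stage = as.integer(messages_per_stage),
                 message_chars = as.integer(message_chars)),
            class = "srf_gen_config")
}

#' Calibrate the model intercept to a target prevalence
#'
#' Solves `E[plogis(beta0 + beta . X)] = target` for `beta0`, where the
#' category counts `X` are independent Poissons with means `lambda_totals`.
#' With all `beta = 0` the closed form `qlogis(target)` is returned; otherwise
#' the expectation is estimated by Monte Carlo (common draws across root
#' evaluations) and solved by 1-D root finding.
#'
#' @param target Target prevalence in (0, 1).
#' @param beta Numeric vector of log-OR coefficients.
#' @param lambda_totals Per-category total Poisson means (same length).
#' @param n_mc Monte-Carlo draws (default 2e5; prevalence error well under
#'   1e-3).
#' @param seed Optional seed for the draws (caller RNG restored).
#' @return The intercept `beta0`.
#' @export
calibrate_intercept <- function(target, beta, lambda_totals, n_mc = 200000,
                                seed = NULL) {
  stopifnot(target > 0, target < 1, length(beta) == length(lambda_totals))
  if (all(beta == 0)) return(qlogis(target))
  s <- with_seed(seed, {
    X <- matrix(rpois(n_mc * length(beta), rep(lambda_totals, each = n_mc)),
                nrow = n_mc)
    as.numeric(X %*% beta)
  })
  calibrate_b0_given_lp(s, target)
}

calibrate_b0_given_lp <- function(s, target) {
  f <- function(b0) mean(plogis(b0 + s)) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) stop("target prevalence unattainable")
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Default generator configuration
#'
#' The study conditions the generator emulates: 17,564 sessions; joint
#' gender/age cell probabilities proportional to the reference subgroup table
#' ([crisis_sample_table()], independence across the two margins); per-cell
#' target prevalences combining the gender and age margins additively on the
#' log-odds scale; true per-mention odds ratios set to the reported
#' gender-specific point estimates (previous attempt 1.29 women / 1.26 men,
#' hopelessness 1.24 / 1.29, self-harm 1.17 / 1.16, thwarted belongingness
#' 1.06 / 1.12, loneliness 1.07 in women only, depression 1.03 in men only,
#' protective bullying 0.91 in women) and 1.0 elsewhere; stage-uniform Poisson
#' intensities of 0.3 mentions per category per stage (1.5 per chat), with a
#' late-stage-weighted profile for depression and thwarted belongingness.
#' Intercepts are calibrated per cell by [calibrate_intercept()].
#'
#' @param lexicon A compiled `srf_lexicon` whose categories include the named
#'   constructs (default the packaged toy lexicon).
#' @param n_sessions Corpus size (default 17,564).
#' @param lambda_per_chat Total expected mentions per category per chat
#'   (default 1.5).
#' @param n_mc,calibration_seed Monte-Carlo settings for intercept
#'   calibration; the fixed default seed makes the configuration
#'   deterministic.
#' @return An `srf_gen_config`.
#' @export
default_config <- function(lexicon = toy_lexicon(), n_sessions = 17564,
                           lambda_per_chat = 1.5, n_mc = 200000,
                           calibration_seed = 104729) {
  ids <- lexicon_categories(lexicon)
  K <- length(ids)
  need <- c("previous_attempt", "hopelessness", "self_harm", "loneliness",
            "thwarted_belongingness", "bullying", "depression")
  miss <- setdiff(need, ids)
  if (length(miss)) stop("lexicon lacks required categories: ",
                         paste(miss, collapse = ", "))
  tab <- crisis_sample_table()
  g <- tab[tab$dimension == "gender", ]
  a <- tab[tab$dimension == "age", ]
  p_all <- tab$prevalence[tab$subgroup == "all"][1]
  cell_probs <- outer(g$n_total / sum(g$n_total), a$n_total / sum(a$n_total))
  cell_prev <- plogis(outer(qlogis(g$prevalence), qlogis(a$prevalence), "+") -
                        qlogis(p_all))

  true_beta <- matrix(0, K, 3, dimnames = list(ids, srf_genders))
  true_beta["previous_attempt", c("female", "male")]       <- log(c(1.29, 1.26))
  true_beta["hopelessness", c("female", "male")]           <- log(c(1.24, 1.29))
  true_beta["self_harm", c("female", "male")]              <- log(c(1.17, 1.16))
  true_beta["thwarted_belongingness", c("female", "male")] <- log(c(1.06, 1.12))
  true_beta["loneliness", "female"]                        <- log(1.07)
  true_beta["depression", "male"]                          <- log(1.03)
  true_beta["bullying", "female"]                          <- log(0.91)
  true_beta[, "unknown"] <- rowMeans(true_beta[, c("female", "male")])

  stage_rates <- matrix(lambda_per_chat / 5, K, 5,
                        dimnames = list(ids, paste0("stage", 1:5)))
  late <- c(0.4, 0.7, 1.0, 1.3, 1.6)  # sums to 5: same per-chat total
  stage_rates["depression", ] <- lambda_per_chat * late / 5
  stage_rates["thwarted_belongingness", ] <- lambda_per_chat * late / 5

  lambda_totals <- rowSums(stage_rates)
  beta0 <- matrix(NA_real_, 3, 5, dimnames = list(srf_genders, srf_age_groups))
  for (gi in seq_len(3)) {
    s <- with_seed(calibration_seed + gi, {
      X <- matrix(rpois(n_mc * K, rep(lambda_totals, each = n_mc)), nrow = n_mc)
      as.numeric(X %*% true_beta[, gi])
    })
    for (ai in seq_len(5)) beta0[gi, ai] <- calibrate_b0_given_lp(s, cell_prev[gi, ai])
  }
  generator_config(n_sessions, cell_probs, stage_rates, true_beta,
                   beta0 = beta0, cell_prevalence = cell_prev)
}

# ---- corpus generation -----------------------------------------------------

#' Generate a synthetic chat corpus with known ground truth
#'
#' For each session: draw a (gender, age) cell; draw per-category per-stage
#' planted counts from the configured Poisson intensities; draw the SR label
#' from the logistic model on the total counts; and (optionally) render the
#' five stages as padded help-seeker messages interleaved with counselor
#' filler, embedding exactly the planted phrase occurrences. By construction
#' the matcher recovers the planted counts exactly and character-fraction
#' slicing at f = s/5 captures exactly stages 1..s.
#'
#' @param config An `srf_gen_config`.
#' @param lexicon A compiled `srf_lexicon` with the config's categories.
#' @param seed Optional integer seed (caller RNG restored); identical
#'   config + seed gives an identical corpus.
#' @param render_text Render message text (default `TRUE`). With `FALSE` only
#'   the ground truth (counts, labels, demographics) is produced - the fast
#'   path for statistical simulation studies that do not exercise the matcher.
#' @return List with `sessions` (list of `chat_session`, or `NULL`) and
#'   `ground_truth` (class `srf_ground_truth`): per-session tibble, count
#'   matrices (`counts_total`, `counts_stage`), `true_beta`, `beta0`, config.
#' @export
generate_corpus <- function(config, lexicon = NULL, seed = NULL,
                            render_text = TRUE) {
  stopifnot(inherits(config, "srf_gen_config"))
  if (render_text && is.null(lexicon)) {
    stop("a compiled lexicon is required to render text")
  }
  ids <- config$categories
  if (!is.null(lexicon)) {
    if (!identical(sort(config$categories), sort(lexicon_categories(lexicon)))) {
      stop("config categories do not match lexicon categories")
    }
    ids <- lexicon_categories(lexicon)
  }
  if (is.null(config$beta0)) {
    stop("config has no calibrated beta0; build it with default_config() or ",
         "supply beta0 to generator_config()")
  }
  if (render_text) validate_plantable(lexicon, config$filler)
  with_seed(seed, {
    n <- config$n_sessions
    K <- length(ids)
    lam <- config$stage_rates[ids, , drop = FALSE]
    cell <- sample.int(15L, n, replace = TRUE, prob = as.vector(config$cell_probs))
    gi <- ((cell - 1L) %% 3L) + 1L          # row index: gender
    ai <- ((cell - 1L) %/% 3L) + 1L         # column index: age group
    gender <- srf_genders[gi]
    age_group <- srf_age_groups[ai]
    counts_stage <- array(rpois(n * K * 5, rep(as.vector(lam), each = n)),
                          dim = c(n, K, 5), dimnames = list(NULL, ids, NULL))
    counts_total <- matrix(0, n, K, dimnames = list(NULL, ids))
    for (s in 1:5) counts_total <- counts_total + matrix(counts_stage[, , s], n, K)
    lp <- config$beta0[cbind(gi, ai)]
    for (g in seq_len(3)) {
      rows <- which(gi == g)
      if (length(rows)) {
        lp[rows] <- lp[rows] +
          as.numeric(counts_total[rows, , drop = FALSE] %*% config$true_beta[, g])
      }
    }
    y <- rbinom(n, 1, plogis(lp))
    session_id <- sprintf("s%06d", seq_len(n))
    gt_sessions <- tibble::tibble(session_id = session_id, gender = gender,
                                  age_group = age_group, sr_label = y,
                                  linear_predictor = lp)
    sessions <- NULL
    if (render_text) {
      sessions <- render_sessions(session_id, gender, age_group, y,
                                  counts_stage, lexicon, config)
    }
    ground_truth <- structure(
      list(sessions = gt_sessions, counts_total = counts_total,
           counts_stage = counts_stage, true_beta = config$true_beta,
           beta0 = config$beta0, config = config),
      class = "srf_ground_truth")
    list(sessions = sessions, ground_truth = ground_truth)
  })
}

render_sessions <- function(session_id, gender, age_group, y, counts_stage,
                            lexicon, config) {
  n <- length(session_id)
  ids <- lexicon_categories(lexicon)
  phrase_pool <- lapply(lexicon$categories, function(cc) {
    vapply(cc$compiled, `[[`, "", "clean")
  })
  fb <- filler_by_length(config$filler)
  m <- config$messages_per_stage
  spk <- rep(c("counselor", "help_seeker"), times = 5 * m)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    # planted phrase strings per (stage, message)
    units <- vector("list", 5 * m)
    for (s in 1:5) {
      cnt <- counts_stage[i, , s]
      hot <- which(cnt > 0)
      if (length(hot)) {
        occ <- unlist(lapply(hot, function(k) {
          sample(phrase_pool[[k]], cnt[k], replace = TRUE)
        }), use.names = FALSE)
        occ <- occ[sample.int(length(occ))]
        slot <- sample.int(m, length(occ), replace = TRUE)
        for (k in seq_len(m)) {
          units[[(s - 1L) * m + k]] <- occ[slot == k]
        }
      }
    }
    contents <- vapply(units, function(u) {
      if (!length(u)) return("")
      if (length(u) > 1L) {
        sep_fill <- sample(config$filler, length(u) - 1L, replace = TRUE)
        u <- c(rbind(u[-length(u)], sep_fill), u[length(u)])
      }
      paste(u, collapse = " ")
    }, character(1))
    L <- max(config$message_chars, max(stringi::stri_length(contents)) + 2L)
    hs_texts <- vapply(contents, pad_to_length, character(1), L = L, fb = fb,
                       USE.NAMES = FALSE)
    cn <- 5L * m
    counselor <- vapply(seq_len(cn), function(j) {
      paste(sample(config$filler, sample(3:6, 1), replace = TRUE), collapse = " ")
    }, character(1))
    texts <- character(2L * cn)
    texts[seq(1L, 2L * cn, by = 2L)] <- counselor
    texts[seq(2L, 2L * cn, by = 2L)] <- hs_texts
    out[[i]] <- chat_session(session_id[i],
                             data.frame(speaker = spk, text = texts,
                                        stringsAsFactors = FALSE),
                             gender = gender[i], age_group = age_group[i],
                             sr_label = y[i])
  }
  out
}

# Pad `content` with filler tokens to exactly L cleaned characters. Guarantees
# at least one appended filler token whenever content is non-empty (callers
# ensure L >= nchar(content) + 2), so messages always end in filler.
pad_to_length <- function(content, L, fb) {
  cur <- stringi::stri_length(content)
  if (cur > L - 2L && cur != L) stop("internal: padding target too tight")
  if (cur == 0L) {
    t <- if (L <= 10L) L else if (L == 11L) 9L else 10L
    content <- sample(fb[[t]], 1)
    cur <- t
  }
  while (cur < L) {
    gap <- L - cur
    if (gap < 2L) stop("internal: unpaddable gap of 1")
    t <- if (gap <= 11L) gap - 1L else 5L
    content <- paste(content, sample(fb[[t]], 1))
    cur <- cur + t + 1L
  }
  content
}

#' @export
print.srf_ground_truth <- function(x, ...) {
  cat("<srf_ground_truth> n=", nrow(x$sessions),
      ", categories=", ncol(x$counts_total),
      ", realized prevalence=", round(mean(x$sessions$sr_label), 4), "\n", sep = "")
  invisible(x)
}

#' Feature table from generator ground truth
#'
#' Builds the same `srf_features` tibble that [featurize_sessions()] would
#' produce from the rendered corpus, directly from the planted per-stage
#' counts: the count at fraction f = s/5 is the cumulative sum of stages
#' 1..s. This is the generator's count-level fast path; its agreement with
#' the text pipeline is asserted exactly by the end-to-end recovery tests.
#'
#' @param ground_truth An `srf_ground_truth`.
#' @param fraction One of 0.2, 0.4, 0.6, 0.8, 1.0.
#' @return An `srf_features` tibble.
#' @export
ground_truth_features <- function(ground_truth, fraction = 1) {
  stopifnot(inherits(ground_truth, "srf_ground_truth"))
  s <- round(fraction * 5)
  if (abs(fraction * 5 - s) > 1e-9 || s < 1 || s > 5) {
    stop("fraction must be one of ", paste(srf_fractions, collapse = ", "))
  }
  cs <- ground_truth$counts_stage
  counts <- matrix(0, dim(cs)[1], dim(cs)[2], dimnames = dimnames(cs)[1:2])
  for (j in 1:s) counts <- counts + matrix(cs[, , j], dim(cs)[1], dim(cs)[2])
  meta <- ground_truth$sessions
  out <- tibble::as_tibble(cbind(
    tibble::tibble(session_id = meta$session_id, gender = meta$gender,
                   age_group = meta$age_group, sr_label = meta$sr_label,
                   fraction = fraction),
    tibble::as_tibble(matrix(as.numeric(counts), nrow = nrow(counts),
                             dimnames = dimnames(counts)))))
  attr(out, "categories") <- colnames(counts)
  class(out) <- c("srf_features", class(out))
  out
}
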