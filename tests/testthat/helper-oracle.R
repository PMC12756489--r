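# Independent brute-force matching oracle and random instance generators.
#
# The oracle enumerates ALL candidate matches by attempting an anchored PCRE
# match at every character position (base-R regexpr; a different engine and a
# different enumeration strategy than the package's lazy scan), then selects
# non-overlapping matches greedily by leftmost start, longest at ties.

oracle_candidates <- function(text, phrase) {
  txt <- tolower(text)
  toks <- strsplit(tolower(phrase), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("oracle: empty phrase")
  pat <- paste0("^", paste(toks, collapse = "[^a-z0-9]+"), "(?![a-z0-9])")
  n <- nchar(txt)
  if (n == 0) return(cbind(start = integer(0), end = integer(0)))
  subs <- substring(txt, 1:n, n)
  m <- regexpr(pat, subs, perl = TRUE)
  chars <- strsplit(txt, "")[[1]]
  word_before <- c(FALSE, grepl("[a-z0-9]", chars[-n]))
  ok <- m == 1 & !word_before
  starts <- which(ok)
  cbind(start = starts, end = starts + attr(m, "match.length")[ok] - 1L)
}

oracle_greedy <- function(cand) {
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand[, 1], -cand[, 2]), , drop = FALSE]
  sel <- matrix(integer(0), 0, 2)
  pos <- 0L
  for (r in seq_len(nrow(cand))) {
    if (cand[r, 1] > pos) {
      sel <- rbind(sel, cand[r, ])
      pos <- cand[r, 2]
    }
  }
  sel
}

# lexicon_list: named list of character vectors (category -> phrases)
oracle_count_matches <- function(lexicon_list, text) {
  vapply(lexicon_list, function(phrases) {
    cand <- do.call(rbind, lapply(phrases, oracle_candidates, text = text))
    nrow(oracle_greedy(cand))
  }, integer(1))
}

# Random lexicons over a small token pool with heavy overlap, to stress
# boundary, tie-break and cross-phrase interactions.
random_lexicon_list <- function() {
  pool <- c("a", "b", "c", "ab", "ba", "aa", "abc", "cb")
  n_cat <- sample(1:5, 1)
  out <- lapply(seq_len(n_cat), function(k) {
    n_ph <- sample(1:5, 1)
    vapply(seq_len(n_ph), function(j) {
      paste(sample(pool, sample(1:3, 1), replace = TRUE), collapse = " ")
    }, character(1))
  })
  names(out) <- paste0("cat", seq_len(n_cat))
  out
}

random_match_text <- function(max_chars = 500) {
  pool <- c("a", "b", "c", "ab", "ba", "aa", "abc", "cb", "x", "zz")
  seps <- c(" ", "  ", ", ", ". ", ",", "-")
  n_tok <- sample(1:60, 1)
  toks <- sample(pool, n_tok, replace = TRUE)
  caps <- runif(n_tok) < 0.2
  toks[caps] <- toupper(toks[caps])
  txt <- paste(toks, collapse = sample(seps, 1))
  substr(txt, 1, max_chars)
}

as_srf_lexicon <- function(lexicon_list) {
  compile_lexicon(srf_lexicon(lapply(lexicon_list, function(p) list(phrases = p))))
}

# Small handmade session helpers -------------------------------------------

make_session <- function(id = "s1", hs_texts, cs_texts = NULL,
                         gender = "female", age_group = "21-40", sr_label = 0) {
  speakers <- rep("help_seeker", length(hs_texts))
  texts <- hs_texts
  if (!is.null(cs_texts)) {
    speakers <- as.vector(rbind(rep("counselor", length(hs_texts)), speakers))
    texts <- as.vector(rbind(cs_texts, hs_texts))
  }
  chat_session(id, data.frame(speaker = speakers, text = texts),
               gender = gender, age_group = age_group, sr_label = sr_label)
}

random_session <- function(id, n_msg = sample(2:8, 1)) {
  words <- c("zim", "vop", "kex", "quab", "zorp", "blorp", "no hope", "so lonely")
  texts <- vapply(seq_len(n_msg), function(i) {
    paste(sample(words, sample(3:10, 1), replace = TRUE), collapse = " ")
  }, character(1))
  speakers <- sample(c("help_seeker", "counselor"), n_msg, replace = TRUE)
  speakers[sample(n_msg, 1)] <- "help_seeker"  # ensure at least one
  chat_session(id, data.frame(speaker = speakers, text = texts),
               gender = sample(c("female", "male", "unknown"), 1),
               age_group = sample(c("10-17", "18-20", "21-40", "41+", "unknown"), 1),
               sr_label = sample(0:1, 1))
}

# Tiny two-construct generator configuration for fast statistical tests.
small_gen_config <- function(n, beta_late = log(2.5), beta_flat = 0,
                             lam_late = c(1, 1.5, 2.25, 3.4, 5),
                             lam_flat = rep(0.3, 5), prev = 0.2) {
  rates <- rbind(late = lam_late, flat = lam_flat)
  beta <- matrix(c(beta_late, beta_flat), 2, 3,
                 dimnames = list(c("late", "flat"), c("female", "male", "unknown")))
  cp <- matrix(0, 3, 5); cp[1, 3] <- 1
  b0 <- calibrate_intercept(prev, beta[, 1], rowSums(rates), seed = 7)
  generator_config(n, cp, rates, beta, beta0 = matrix(b0, 3, 5))
}
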