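# Lexicon engine: load, compile and apply a phrase lexicon of psychological
# constructs to cleaned chat text.
#
# Matching semantics (fixed by design):
#   * a phrase is a sequence of word tokens; any run of non-letter/non-digit
#     characters between tokens matches as a single separator;
#   * matches are anchored at word boundaries, defined as transitions between
#     letter/digit characters and everything else (language neutral: works for
#     Hebrew as well as Latin scripts);
#   * case is folded and text is Unicode NFC-normalised;
#   * no stemming, no lemmatisation, no fuzzy matching;
#   * per category, counting selects non-overlapping matches from the pooled
#     candidates of all its phrases by a left-to-right scan preferring the
#     leftmost start and, at equal start, the longest match;
#   * categories are counted independently: one text span may count in
#     several categories.

WORD_CHAR <- "[\\p{L}\\p{N}]"

#' Construct a suicide-risk-factor lexicon
#'
#' A lexicon is an ordered set of categories (psychological constructs such as
#' hopelessness or loneliness), each holding an ordered set of phrases.
#' Category order is fixed and defines the feature-column order downstream.
#'
#' @param categories Named list. Each element is a list with `label` (display
#'   name) and `phrases` (character vector, at least one phrase); names are the
#'   category ids.
#' @param settings List of matching options: `case_fold` (default `TRUE`) and
#'   `word_boundaries` (default `TRUE`).
#' @return An object of class `srf_lexicon`.
#' @seealso [load_lexicon()], [compile_lexicon()], [count_matches()]
#' @export
#' @examples
#' lex <- srf_lexicon(list(
#'   hopelessness = list(label = "Hopelessness", phrases = c("no hope", "hopeless")),
#'   loneliness   = list(label = "Loneliness",   phrases = "all alone")
#' ))
#' count_matches(compile_lexicon(lex), "i feel hopeless. there is no hope.")
srf_lexicon <- function(categories, settings = list()) {
  if (!length(categories)) stop("lexicon must contain at least one category")
  ids <- names(categories)
  if (is.null(ids) || any(!nzchar(ids))) stop("every category needs a non-empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate category id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  categories <- lapply(seq_along(categories), function(i) {
    cat <- categories[[i]]
    phrases <- as.character(cat$phrases)
    phrases <- phrases[!is.na(phrases)]
    if (!length(phrases)) stop("category '", ids[i], "' has zero phrases")
    list(id = ids[i],
         label = if (is.null(cat$label)) ids[i] else as.character(cat$label),
         phrases = phrases)
  })
  names(categories) <- ids
  settings <- modifyList(list(case_fold = TRUE, word_boundaries = TRUE), settings)
  structure(list(categories = categories, settings = settings, compiled = FALSE),
            class = "srf_lexicon")
}

#' @export
print.srf_lexicon <- function(x, ...) {
  cat("<srf_lexicon> ", length(x$categories), " categories",
      if (isTRUE(x$compiled)) " (compiled)", "\n", sep = "")
  np <- vapply(x$categories, function(cc) length(cc$phrases), integer(1))
  cat(" phrases per category: ", paste0(names(np), "=", np, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Category ids of a lexicon, in feature-column order
#' @param lexicon An `srf_lexicon`.
#' @return Character vector of category ids.
#' @export
lexicon_categories <- function(lexicon) {
  stopifnot(inherits(lexicon, "srf_lexicon"))
  names(lexicon$categories)
}

#' Load a lexicon from a file
#'
#' Reads the delimited lexicon format: a UTF-8 TSV with header
#' `category_id<TAB>label<TAB>phrase`, one phrase per row. Categories keep file
#' order; a category's rows must be contiguous (a category id re-appearing
#' after another category is treated as a duplicate id). YAML/JSON config
#' documents with fields `categories: [{id, label, phrases}]` and optional
#' `settings` are accepted as well, chosen by file extension.
#'
#' @param path Path to a `.tsv`/`.txt`, `.json` or `.yaml`/`.yml` file.
#' @return An (uncompiled) `srf_lexicon`.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("the 'yaml' package is required for YAML lexicons")
    doc <- yaml::read_yaml(path)
    return(lexicon_from_doc(doc))
  }
  if (ext == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    return(lexicon_from_doc(doc))
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = "character", fileEncoding = "UTF-8")
  if (!nrow(tab)) stop("empty lexicon file: ", path)
  need <- c("category_id", "label", "phrase")
  if (!all(need %in% names(tab))) {
    stop("lexicon file must have columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(tab$category_id)
  # contiguity check: a block restarting an earlier id is a duplicate definition
  runs <- rle(tab$category_id)$values
  if (anyDuplicated(runs)) {
    stop("duplicate category id(s) in lexicon file: ",
         paste(unique(runs[duplicated(runs)]), collapse = ", "))
  }
  categories <- lapply(ids, function(id) {
    rows <- tab[tab$category_id == id, , drop = FALSE]
    list(label = rows$label[1], phrases = rows$phrase)
  })
  names(categories) <- ids
  srf_lexicon(categories)
}

lexicon_from_doc <- function(doc) {
  if (is.null(doc$categories) || !length(doc$categories)) {
    stop("lexicon document must contain a non-empty 'categories' list")
  }
  categories <- list()
  for (cat in doc$categories) {
    if (is.null(cat$id)) stop("lexicon document category missing 'id'")
    if (cat$id %in% names(categories)) stop("duplicate category id(s): ", cat$id)
    categories[[cat$id]] <- list(label = cat$label, phrases = unlist(cat$phrases))
  }
  settings <- if (is.null(doc$settings)) list() else doc$settings
  srf_lexicon(categories, settings)
}

#' Write a lexicon to the delimited TSV format
#'
#' Round-trips with [load_lexicon()].
#'
#' @param lexicon An `srf_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "srf_lexicon"))
  rows <- do.call(rbind, lapply(lexicon$categories, function(cc) {
    data.frame(category_id = cc$id, label = cc$label, phrase = cc$phrases,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged 20-category toy lexicon
#'
#' A small English stand-in for a full suicide-risk-factor lexicon: the same
#' 20 construct categories, a handful of phrases each. Intended for examples,
#' tests and synthetic corpora, not for analysing real chats.
#'
#' @param compiled Compile the lexicon before returning (default `TRUE`).
#' @return An `srf_lexicon` with exactly 20 categories.
#' @export
toy_lexicon <- function(compiled = TRUE) {
  path <- system.file("extdata", "srf_toy_lexicon.tsv", package = "srflex")
  lex <- load_lexicon(path)
  if (compiled) compile_lexicon(lex) else lex
}

# -- compilation ------------------------------------------------------------

normalize_phrase <- function(phrase, case_fold = TRUE) {
  x <- stringi::stri_trans_nfc(phrase)
  if (case_fold) x <- stringi::stri_trans_tolower(x)
  x
}

phrase_tokens <- function(phrase, case_fold = TRUE) {
  x <- normalize_phrase(phrase, case_fold)
  toks <- stringi::stri_split_regex(x, paste0("(?:(?!", WORD_CHAR, ").)+"))[[1]]
  toks[nzchar(toks)]
}

compile_phrase <- function(phrase, settings) {
  toks <- phrase_tokens(phrase, settings$case_fold)
  if (!length(toks)) {
    stop("phrase '", phrase, "' reduces to an empty token sequence after normalization")
  }
  sep <- paste0("(?:(?!", WORD_CHAR, ").)+")
  body <- paste(toks, collapse = sep)
  if (isTRUE(settings$word_boundaries)) body <- paste0(body, "(?!", WORD_CHAR, ")")
  list(raw = phrase,
       clean = paste(toks, collapse = " "),
       pattern = body,
       n_tokens = length(toks))
}

#' Compile a lexicon's phrases to deterministic matchers
#'
#' Every phrase becomes a matcher that folds case, tolerates any run of
#' whitespace/punctuation between tokens, anchors at word boundaries and
#' applies Unicode NFC normalization. No stemming and no fuzzy matching.
#'
#' @param lexicon An `srf_lexicon`.
#' @return The lexicon with compiled patterns attached.
#' @export
compile_lexicon <- function(lexicon) {
  stopifnot(inherits(lexicon, "srf_lexicon"))
  lexicon$categories <- lapply(lexicon$categories, function(cc) {
    cc$compiled <- lapply(cc$phrases, compile_phrase, settings = lexicon$settings)
    cc
  })
  lexicon$compiled <- TRUE
  lexicon
}

regex_opts <- function(settings) {
  stringi::stri_opts_regex(case_insensitive = isTRUE(settings$case_fold))
}

is_word_char <- function(ch) {
  nzchar(ch) && stringi::stri_detect_regex(ch, paste0("^", WORD_CHAR))
}

# Leftmost match of `pattern` in `text` starting at or after 1-based `from`,
# whose start position sits on a word boundary. Returns c(start, end)
# (1-based, inclusive) or c(NA, NA).
next_match <- function(text, pattern, from, opts, boundaries = TRUE) {
  n <- stringi::stri_length(text)
  while (from <= n) {
    m <- stringi::stri_locate_first_regex(stringi::stri_sub(text, from, n),
                                          pattern, opts_regex = opts)
    if (is.na(m[1, 1])) break
    s <- from + m[1, 1] - 1L
    e <- from + m[1, 2] - 1L
    if (!boundaries || s == 1L || !is_word_char(stringi::stri_sub(text, s - 1L, s - 1L))) {
      return(c(s, e))
    }
    from <- s + 1L
  }
  c(NA_integer_, NA_integer_)
}

# Greedy leftmost-longest selection of non-overlapping matches for one
# category. Candidate streams per phrase are advanced lazily, so all candidate
# starts (including starts inside other phrases' matches) are considered.
match_category <- function(text, patterns, opts, boundaries = TRUE) {
  nph <- length(patterns)
  cs <- rep(NA_integer_, nph)
  ce <- rep(NA_integer_, nph)
  stale <- rep(TRUE, nph)
  pos <- 1L
  out_s <- integer(0); out_e <- integer(0); out_p <- integer(0)
  repeat {
    refresh <- which(stale | (!is.na(cs) & cs < pos))
    for (i in refresh) {
      m <- next_match(text, patterns[[i]], pos, opts, boundaries)
      cs[i] <- m[1]; ce[i] <- m[2]
    }
    stale[] <- FALSE
    live <- which(!is.na(cs))
    if (!length(live)) break
    best <- live[order(cs[live], -ce[live])][1]
    out_s <- c(out_s, cs[best]); out_e <- c(out_e, ce[best]); out_p <- c(out_p, best)
    pos <- ce[best] + 1L
    stale[best] <- TRUE
  }
  list(start = out_s, end = out_e, phrase = out_p)
}

# Batch matcher over a character vector of cleaned texts.
#
# Fast path: per phrase, a vectorised non-overlapping scan collects candidate
# spans for all texts at once. When a text's pooled candidates for a category
# are pairwise disjoint and all leading boundaries check out, greedy selection
# keeps every candidate, and candidates hidden by the non-overlapping scan
# (starts inside another match of the same phrase) cannot change the result -
# so the pooled set IS the answer. Otherwise the text falls back to the exact
# lazy merge scan (match_category), which enumerates all candidate starts.
#
# Returns list(counts = n x K integer matrix, spans = list of data.frames or NULL).
match_engine <- function(lexicon, texts, spans = FALSE) {
  stopifnot(inherits(lexicon, "srf_lexicon"))
  if (!isTRUE(lexicon$compiled)) stop("lexicon must be compiled; see compile_lexicon()")
  texts <- as.character(texts)
  texts[is.na(texts)] <- ""
  texts <- stringi::stri_trans_nfc(texts)
  n <- length(texts)
  ids <- lexicon_categories(lexicon)
  K <- length(ids)
  opts <- regex_opts(lexicon$settings)
  boundaries <- isTRUE(lexicon$settings$word_boundaries)
  counts <- matrix(0L, nrow = n, ncol = K, dimnames = list(NULL, ids))
  span_out <- if (spans) vector("list", n) else NULL

  for (k in seq_len(K)) {
    cc <- lexicon$categories[[k]]
    patterns <- lapply(cc$compiled, `[[`, "pattern")
    cand <- vector("list", n)  # per text: rbind of (start, end, phrase)
    for (pi in seq_along(patterns)) {
      loc <- stringi::stri_locate_all_regex(texts, patterns[[pi]],
                                            omit_no_match = TRUE,
                                            opts_regex = opts)
      for (i in which(lengths(loc) > 0L & vapply(loc, nrow, 0L) > 0L)) {
        cand[[i]] <- rbind(cand[[i]], cbind(loc[[i]], phrase = pi))
      }
    }
    for (i in which(!vapply(cand, is.null, TRUE))) {
      cm <- cand[[i]]
      ord <- order(cm[, 1], -cm[, 2])
      cm <- cm[ord, , drop = FALSE]
      ok_boundary <- !boundaries || all(
        cm[, 1] == 1L |
          !stringi::stri_detect_regex(
            stringi::stri_sub(texts[i], cm[, 1] - 1L, cm[, 1] - 1L),
            paste0("^", WORD_CHAR)))
      disjoint <- nrow(cm) == 1L ||
        all(cm[-1L, 1] > cm[-nrow(cm), 2])
      if (ok_boundary && disjoint) {
        mm <- list(start = cm[, 1], end = cm[, 2], phrase = cm[, 3])
      } else {
        mm <- match_category(texts[i], patterns, opts, boundaries)
      }
      counts[i, k] <- length(mm$start)
      if (spans && length(mm$start)) {
        span_out[[i]] <- rbind(span_out[[i]], data.frame(
          category_id = ids[k],
          phrase_index = as.integer(mm$phrase),
          phrase = vapply(cc$compiled[mm$phrase], `[[`, "", "raw"),
          start = as.integer(mm$start) - 1L,   # 0-based half-open offsets
          end = as.integer(mm$end),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (spans) {
    span_out <- lapply(span_out, function(df) {
      if (is.null(df)) {
        data.frame(category_id = character(0), phrase_index = integer(0),
                   phrase = character(0), start = integer(0), end = integer(0),
                   stringsAsFactors = FALSE)
      } else {
        df[order(df$start, df$category_id), , drop = FALSE]
      }
    })
  }
  list(counts = counts, spans = span_out)
}

#' Count lexicon matches per category in a cleaned text
#'
#' For each category, counts non-overlapping matches found by a single
#' left-to-right scan over the union of the category's phrases, preferring the
#' leftmost match and, at equal start, the longest. Categories are counted
#' independently, so one text span may count in two categories.
#'
#' @param lexicon A compiled `srf_lexicon`.
#' @param text A single character string, already cleaned (see [clean_text()]).
#' @return Named integer vector, one non-negative count per category.
#' @export
count_matches <- function(lexicon, text) {
  stopifnot(length(text) == 1L)
  match_engine(lexicon, text)$counts[1, ]
}

#' Explain lexicon matches as character spans
#'
#' Returns the spans behind [count_matches()]: per category, exactly as many
#' spans as the count, with 0-based half-open `[start, end)` offsets into the
#' given text, sorted by start.
#'
#' @inheritParams count_matches
#' @return A data frame with columns `category_id`, `phrase_index`, `phrase`,
#'   `start`, `end`.
#' @export
explain_matches <- function(lexicon, text) {
  stopifnot(length(text) == 1L)
  match_engine(lexicon, text, spans = TRUE)$spans[[1]]
}
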