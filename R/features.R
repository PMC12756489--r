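# Turn sessions plus a compiled lexicon into per-session feature vectors and
# design matrices for the logistic models.

#' Vectorize one session into category counts
#'
#' Applies [count_matches()] to the concatenated cleaned help-seeker text of
#' `slice_prefix(session, fraction)`. Column order is lexicon category order.
#'
#' @param session A `chat_session`.
#' @param lexicon A compiled `srf_lexicon`.
#' @param fraction Progress fraction (default 1.0, the full chat).
#' @param normalize Scale counts to matches per 1,000 help-seeker characters
#'   (default `FALSE`: raw counts, so odds ratios are per-mention effects).
#' @param presence Reduce counts to binary presence (default `FALSE`).
#' @return Named numeric vector, one entry per category, with attributes
#'   `session_id` and `fraction`.
#' @export
vectorize_session <- function(session, lexicon, fraction = 1,
                              normalize = FALSE, presence = FALSE) {
  sl <- slice_prefix(session, fraction)
  txt <- helpseeker_text(sl)
  counts <- as.numeric(count_matches(lexicon, txt))
  names(counts) <- lexicon_categories(lexicon)
  if (presence) counts <- pmin(counts, 1)
  if (normalize) {
    nchars <- stringi::stri_length(txt)
    counts <- if (nchars > 0) 1000 * counts / nchars else counts
  }
  structure(counts, session_id = session$session_id, fraction = fraction)
}

#' Build a feature table for a corpus of sessions
#'
#' One row per session: metadata, SR label, progress fraction, and one count
#' column per lexicon category (in lexicon order).
#'
#' @param sessions List of `chat_session` objects.
#' @param lexicon A compiled `srf_lexicon`.
#' @inheritParams vectorize_session
#' @return A tibble of class `srf_features` with attribute `categories`.
#' @export
featurize_sessions <- function(sessions, lexicon, fraction = 1,
                               normalize = FALSE, presence = FALSE) {
  stopifnot(length(sessions) > 0)
  ids <- lexicon_categories(lexicon)
  if (fraction < 1) sessions <- lapply(sessions, slice_prefix, f = fraction)
  texts <- vapply(sessions, helpseeker_text, character(1))
  counts <- match_engine(lexicon, texts)$counts
  counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  if (presence) counts <- pmin(counts, 1)
  if (normalize) {
    nchars <- stringi::stri_length(texts)
    scale <- ifelse(nchars > 0, 1000 / nchars, 1)
    counts <- counts * scale
  }
  meta <- tibble::tibble(
    session_id = vapply(sessions, `[[`, character(1), "session_id"),
    gender     = vapply(sessions, `[[`, character(1), "gender"),
    age_group  = vapply(sessions, `[[`, character(1), "age_group"),
    sr_label   = vapply(sessions, `[[`, integer(1), "sr_label"),
    fraction   = fraction
  )
  out <- tibble::as_tibble(cbind(meta, tibble::as_tibble(counts)))
  attr(out, "categories") <- ids
  class(out) <- c("srf_features", class(out))
  out
}

feature_categories <- function(features) {
  cats <- attr(features, "categories")
  if (is.null(cats)) {
    cats <- setdiff(names(features),
                    c("session_id", "gender", "age_group", "sr_label", "fraction"))
  }
  cats
}

#' Assemble a design matrix from a feature table
#'
#' Optionally restricts to one stratum. Sessions with unknown gender (for
#' gender strata) or unknown age (for age strata) are excluded from stratified
#' designs but always included in the unstratified "all" design. The intercept
#' column of ones is appended last.
#'
#' @param features An `srf_features` tibble from [featurize_sessions()] or
#'   [ground_truth_features()].
#' @param stratum_var `NULL` (no filter), `"gender"` or `"age_group"`.
#' @param stratum_value The stratum to keep, e.g. `"female"` or `"21-40"`.
#' @return An object of class `srf_design`: list with `x` (matrix, columns =
#'   categories then `intercept`), `y` (0/1 outcome), `session_id`, `stratum`.
#' @export
build_design <- function(features, stratum_var = NULL, stratum_value = NULL) {
  cats <- feature_categories(features)
  df <- as.data.frame(features)
  stratum <- "all"
  if (!is.null(stratum_var)) {
    stopifnot(stratum_var %in% c("gender", "age_group"), !is.null(stratum_value))
    df <- df[df[[stratum_var]] == stratum_value & df[[stratum_var]] != "unknown", ,
             drop = FALSE]
    stratum <- stratum_value
  }
  if (!nrow(df)) stop("empty stratum: ", stratum)
  y <- as.integer(df$sr_label)
  if (length(unique(y)) < 2L) {
    stop("single-class outcome in stratum '", stratum, "': cannot fit a logistic model")
  }
  x <- cbind(as.matrix(df[, cats, drop = FALSE]), intercept = 1)
  design_from_counts(x[, cats, drop = FALSE], y,
                     session_id = df$session_id, stratum = stratum,
                     fraction = df$fraction[1])
}

#' Assemble a design matrix directly from a count matrix
#'
#' Low-level constructor used both by [build_design()] and by simulation code
#' that works on the generator's planted count matrices.
#'
#' @param counts Numeric matrix, one column per category (named).
#' @param y Binary outcome vector, same length as `nrow(counts)`.
#' @param session_id Optional row identifiers.
#' @param stratum Stratum description string (default `"all"`).
#' @param fraction Progress fraction the counts were computed at.
#' @return An `srf_design` object.
#' @export
design_from_counts <- function(counts, y, session_id = NULL, stratum = "all",
                               fraction = 1) {
  counts <- as.matrix(counts)
  if (ncol(counts) > 0 && is.null(colnames(counts))) {
    stop("count matrix must have column names")
  }
  y <- as.integer(y)
  stopifnot(nrow(counts) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) {
    stop("single-class outcome in stratum '", stratum, "': cannot fit a logistic model")
  }
  x <- cbind(counts, intercept = 1)
  structure(list(x = x, y = y,
                 session_id = if (is.null(session_id)) as.character(seq_along(y)) else as.character(session_id),
                 stratum = stratum, fraction = fraction),
            class = "srf_design")
}

#' @export
print.srf_design <- function(x, ...) {
  cat("<srf_design> stratum=", x$stratum, ", n=", length(x$y),
      ", prevalence=", round(mean(x$y), 4),
      ", columns=", ncol(x$x), " (incl. intercept), fraction=", x$fraction,
      "\n", sep = "")
  invisible(x)
}

#' Export a feature table to a delimited file
#'
#' Header: `session_id, <category ids...>, sr_label, fraction`.
#'
#' @param features An `srf_features` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  cats <- feature_categories(features)
  df <- as.data.frame(features)[, c("session_id", cats, "sr_label", "fraction")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
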