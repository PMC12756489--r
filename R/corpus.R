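# Chat-session container, text cleaning, prefix slicing, and the JSON Lines
# session record format.

#' Clean raw chat text
#'
#' Unicode NFC normalization; removal of URLs, markup tags and control
#' characters; whitespace runs collapsed to single spaces; trimming; case
#' folding. Idempotent.
#'
#' @param x Character vector of raw message text.
#' @return Character vector of cleaned text.
#' @export
#' @examples
#' clean_text("I  feel <b>hopeless</b>\n")   # "i feel hopeless"
#' clean_text("see https://x.y now")         # "see now"
clean_text <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- stringi::stri_trans_nfc(x)
  x <- stringi::stri_replace_all_regex(x, "(?i)\\b(?:https?://|www\\.)\\S+", " ")
  x <- stringi::stri_replace_all_regex(x, "<[^<>]*>", " ")
  x <- stringi::stri_replace_all_regex(x, "[\\p{Cc}\\p{Cf}]", " ")
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  x <- stringi::stri_trim_both(x)
  stringi::stri_trans_tolower(x)
}

#' Construct a chat session
#'
#' An ordered, speaker-tagged message list with demographic metadata and the
#' binary suicide-risk (SR) label.
#'
#' @param session_id Scalar identifier.
#' @param messages Data frame with columns `speaker`
#'   (`"help_seeker"`/`"counselor"`) and `text`; row order is message order.
#' @param gender One of `"female"`, `"male"`, `"unknown"`.
#' @param age_group One of `"10-17"`, `"18-20"`, `"21-40"`, `"41+"`,
#'   `"unknown"`.
#' @param sr_label 0/1 suicide-risk label.
#' @return An object of class `chat_session`.
#' @export
chat_session <- function(session_id, messages, gender = "unknown",
                         age_group = "unknown", sr_label) {
  messages <- as.data.frame(messages, stringsAsFactors = FALSE)
  if (!nrow(messages)) stop("a session needs at least one message")
  if (!all(c("speaker", "text") %in% names(messages))) {
    stop("messages need 'speaker' and 'text' columns")
  }
  bad <- setdiff(unique(messages$speaker), srf_speakers)
  if (length(bad)) stop("unknown speaker value(s): ", paste(bad, collapse = ", "))
  gender <- match.arg(gender, srf_genders)
  age_group <- match.arg(age_group, srf_age_groups)
  if (length(sr_label) != 1L || is.na(sr_label) || !sr_label %in% c(0, 1)) {
    stop("sr_label must be 0 or 1")
  }
  rownames(messages) <- NULL
  structure(list(session_id = as.character(session_id),
                 messages = messages[, c("speaker", "text")],
                 gender = gender, age_group = age_group,
                 sr_label = as.integer(sr_label)),
            class = "chat_session")
}

#' @export
print.chat_session <- function(x, ...) {
  cat("<chat_session> id=", x$session_id, ", ", nrow(x$messages), " messages, ",
      "gender=", x$gender, ", age=", x$age_group, ", sr_label=", x$sr_label,
      "\n", sep = "")
  invisible(x)
}

#' Concatenated cleaned help-seeker text of a session
#'
#' Only help-seeker messages feed the matcher; counselor text is excluded so
#' intervention language cannot leak into the risk features.
#'
#' @param session A `chat_session`.
#' @return A single cleaned string (messages joined by single spaces).
#' @export
helpseeker_text <- function(session) {
  stopifnot(inherits(session, "chat_session"))
  txt <- clean_text(session$messages$text[session$messages$speaker == "help_seeker"])
  paste(txt[nzchar(txt)], collapse = " ")
}

helpseeker_char_lens <- function(session) {
  is_hs <- session$messages$speaker == "help_seeker"
  lens <- integer(nrow(session$messages))
  lens[is_hs] <- stringi::stri_length(clean_text(session$messages$text[is_hs]))
  list(is_hs = is_hs, lens = lens)
}

#' Slice the prefix of a chat by progress fraction
#'
#' Returns the shortest whole-message prefix whose cumulative help-seeker
#' character count (of cleaned text) reaches `f` times the session's total
#' help-seeker character count; interleaved counselor messages up to that point
#' are retained. `f = 1` returns the session unchanged. Prefixes are nested:
#' `slice_prefix(s, f1)` is contained in `slice_prefix(s, f2)` for `f1 <= f2`.
#' Metadata and the SR label are copied unchanged.
#'
#' With `unit = "messages"` the fraction applies to the number of help-seeker
#' messages instead of characters.
#'
#' @param session A `chat_session`.
#' @param f Progress fraction; one of 0.2, 0.4, 0.6, 0.8, 1.0 unless
#'   `strict = FALSE`.
#' @param unit Slicing unit: `"chars"` (default) or `"messages"`.
#' @param strict Enforce the five canonical stage fractions (default `TRUE`).
#' @return A `chat_session` containing the prefix.
#' @export
slice_prefix <- function(session, f, unit = c("chars", "messages"), strict = TRUE) {
  stopifnot(inherits(session, "chat_session"))
  unit <- match.arg(unit)
  if (length(f) != 1L || is.na(f) || f <= 0 || f > 1) stop("f must be in (0, 1]")
  if (strict && !any(abs(f - srf_fractions) < 1e-9)) {
    stop("f must be one of ", paste(srf_fractions, collapse = ", "),
         " (use strict = FALSE to override)")
  }
  if (f == 1) return(session)
  hs <- helpseeker_char_lens(session)
  if (!any(hs$is_hs)) stop("session ", session$session_id, " has no help-seeker message")
  if (unit == "chars") {
    total <- sum(hs$lens)
    if (total == 0) stop("session ", session$session_id, " has zero help-seeker characters")
    cum <- cumsum(hs$lens)
    cut_idx <- which(hs$is_hs & cum >= f * total - 1e-9)[1]
  } else {
    n_hs <- cumsum(hs$is_hs)
    total <- sum(hs$is_hs)
    cut_idx <- which(hs$is_hs & n_hs >= f * total - 1e-9)[1]
  }
  out <- session
  out$messages <- session$messages[seq_len(cut_idx), , drop = FALSE]
  rownames(out$messages) <- NULL
  out
}

#' Read chat sessions from a JSON Lines file
#'
#' One session per line:
#' `{"session_id": ..., "gender": ..., "age_group": ..., "sr_label": 0|1,
#'   "messages": [{"speaker": "help_seeker"|"counselor", "text": ...}, ...]}`.
#' Unknown gender/age are preserved as `"unknown"`.
#'
#' @param path Path to a UTF-8 JSON Lines file.
#' @return List of `chat_session` objects.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("session file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no session records in ", path)
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) stop("line ", i, ": malformed JSON (",
                                             conditionMessage(e), ")", call. = FALSE))
    need <- c("session_id", "gender", "age_group", "sr_label", "messages")
    miss <- setdiff(need, names(rec))
    if (length(miss)) {
      stop("line ", i, ": missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    tryCatch(chat_session(rec$session_id, rec$messages, rec$gender,
                          rec$age_group, rec$sr_label),
             error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
}

#' Write chat sessions to a JSON Lines file
#'
#' Lossless round trip with [read_sessions()].
#'
#' @param sessions List of `chat_session` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in sessions) {
    stopifnot(inherits(s, "chat_session"))
    rec <- list(session_id = s$session_id, gender = s$gender,
                age_group = s$age_group, sr_label = s$sr_label,
                messages = s$messages)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows"), con)
  }
  invisible(path)
}
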