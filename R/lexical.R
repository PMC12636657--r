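# Detections are the common currency between pipeline stages: one row per
# flagged event, with 0-based half-open character spans into clean_text.
# `start2`/`end2` hold the second span of a repetition pair; `token_index`
# counts non-sentinel tokens within the utterance (0-based).

detection_row <- function(type, text, start, end, start2 = NA_real_,
                          end2 = NA_real_, utterance_index = NA_integer_,
                          token_index = NA_integer_,
                          token_index2 = NA_integer_,
                          justification = NA_character_) {
  data.frame(type = type, text = text, start = start, end = end,
             start2 = start2, end2 = end2,
             utterance_index = utterance_index, token_index = token_index,
             token_index2 = token_index2, justification = justification,
             stringsAsFactors = FALSE)
}

empty_detections <- function() {
  detection_row(character(), character(), numeric(), numeric(), numeric(),
                numeric(), integer(), integer(), integer(), character())
}

#' Combine detection tables
#' @param ... detection data.frames.
#' @export
bind_detections <- function(...) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (!length(dfs)) return(empty_detections())
  do.call(rbind, dfs)
}

#' Serialize detections to JSON
#'
#' Emits one object per detection with keys `type`, `text`, `span`, and, for
#' repetitions, `span2`; a `justification` key is included when present.
#'
#' @param detections detection data.frame.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
detections_to_json <- function(detections, path = NULL) {
  objs <- lapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    o <- list(type = d$type, text = d$text, span = c(d$start, d$end))
    if (!is.na(d$start2)) o$span2 <- c(d$start2, d$end2)
    if (!is.na(d$justification)) o$justification <- d$justification
    o
  })
  if (is.null(path)) return(jsonlite::toJSON(objs, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a keyword set
#'
#' @param name identifier for the set.
#' @param terms character vector of single- or multi-token phrases; lowercased
#'   and deduplicated, must be non-empty.
#' @return list of class `keyword_set`.
#' @export
keyword_set <- function(name, terms) {
  terms <- unique(tolower(trimws(terms)))
  terms <- terms[nzchar(terms)]
  if (!length(terms)) stop("keyword set '", name, "' is empty", call. = FALSE)
  structure(list(name = name, terms = terms), class = "keyword_set")
}

#' Load a keyword set from a plain-text file (one term per line)
#'
#' Lines starting with `#` and blank lines are ignored. A user-supplied file
#' replaces the built-in defaults entirely.
#'
#' @param path file path.
#' @param name set name (defaults to the file name).
#' @export
load_keywords <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  keyword_set(name, lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Default filler keyword set
#'
#' Non-lexical vocalizations (um, uh, er, ...) plus stray single-letter tokens
#' (every letter except the words "a" and "i"). Shipped as an editable file in
#' `inst/extdata/keywords/fillers.txt`; pass your own file to [load_keywords()]
#' to override.
#' @export
default_filler_keywords <- function() {
  load_keywords(system.file("extdata", "keywords", "fillers.txt",
                            package = "cogspeech", mustWork = TRUE),
                name = "fillers")
}

#' Default vague-speech keyword set (non-specific referents)
#' @export
default_vague_keywords <- function() {
  load_keywords(system.file("extdata", "keywords", "vague.txt",
                            package = "cogspeech", mustWork = TRUE),
                name = "vague")
}

# token table restricted to matchable (non-sentinel) tokens, with the
# original 0-based token index retained
matchable_tokens <- function(u) {
  tok <- u$tokens
  tok$token_index <- seq_len(nrow(tok)) - 1L
  tok[!is_sentinel_token(tok$token), , drop = FALSE]
}

#' Case-insensitive token-aligned keyword search
#'
#' Scans an utterance for occurrences of any term in the keyword set. Matches
#' are token-aligned (no substring matches inside longer words); multi-token
#' terms must match consecutive non-sentinel tokens. Overlapping candidate
#' matches are resolved longest-match-first; the result is sorted by span
#' start.
#'
#' @param u an utterance (list with `tokens` as from [preprocess_utterance()]).
#' @param ks a [keyword_set()].
#' @param detection_type type tag stamped on each detection (e.g. `"filler"`).
#' @return detection data.frame.
#' @export
keyword_search <- function(u, ks, detection_type = ks$name) {
  stopifnot(inherits(ks, "keyword_set"))
  tok <- matchable_tokens(u)
  n <- nrow(tok)
  if (n == 0L) return(empty_detections())
  low <- tolower(tok$token)
  term_tokens <- strsplit(ks$terms, "\\s+")

  cand <- list()
  for (tt in term_tokens) {
    L <- length(tt)
    if (L > n) next
    for (i in seq_len(n - L + 1L)) {
      if (all(low[i:(i + L - 1L)] == tt)) {
        cand[[length(cand) + 1L]] <- c(i = i, L = L)
      }
    }
  }
  if (!length(cand)) return(empty_detections())
  cand <- do.call(rbind, cand)
  # longest-match-first, then leftmost
  cand <- cand[order(-cand[, "L"], cand[, "i"]), , drop = FALSE]
  taken <- logical(n)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    span <- cand[r, "i"]:(cand[r, "i"] + cand[r, "L"] - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep[r] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(r) {
    i <- cand[r, "i"]; L <- cand[r, "L"]
    s <- tok$start[i]; e <- tok$end[i + L - 1L]
    detection_row(detection_type,
                  substring_span(u$clean_text, s, e),
                  s, e,
                  utterance_index = u$index,
                  token_index = tok$token_index[i])
  })
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# substring by 0-based half-open span
substring_span <- function(text, start, end) substr(text, start + 1L, end)

#' Comparators for repetition detection
#'
#' `comparator_exact` is case-insensitive string equality (the default);
#' `comparator_lemma` additionally equates trivially inflected forms by
#' stripping common suffixes (plural -s/-es, -ing, -ed) before comparing.
#'
#' @param a,b token surfaces.
#' @export
comparator_exact <- function(a, b) tolower(a) == tolower(b)

#' @rdname comparator_exact
#' @export
comparator_lemma <- function(a, b) {
  strip <- function(x) {
    x <- tolower(x)
    x <- sub("(ing|ed|es)$", "", x)
    x <- sub("(?<=..)s$", "", x, perl = TRUE)
    x
  }
  strip(a) == strip(b)
}

#' Repetition-detection configuration
#'
#' @param window_k number of preceding tokens compared (default 2, the
#'   F1-optimal window for verbatim repetitions).
#' @param comparator token-equality predicate (default [comparator_exact()]).
#' @export
repetition_config <- function(window_k = 2, comparator = comparator_exact) {
  stopifnot(window_k >= 1, is.function(comparator))
  structure(list(window_k = as.integer(window_k), comparator = comparator),
            class = "repetition_config")
}

#' Windowed unigram repetition detector
#'
#' Iterates through an utterance's tokens and flags any token equal (per the
#' comparator) to one of the previous `window_k` seen tokens. Sentinel tokens
#' are skipped entirely and do not consume window slots; punctuation tokens
#' consume slots but never match. When several previous tokens match, only the
#' nearest one is reported (one detection per current token). `span` is the
#' previous occurrence, `span2` the current one.
#'
#' @param u an utterance.
#' @param cfg a [repetition_config()].
#' @return detection data.frame (type `"repetition"`).
#' @export
detect_repetitions <- function(u, cfg = repetition_config()) {
  stopifnot(inherits(cfg, "repetition_config"))
  tok <- matchable_tokens(u)
  n <- nrow(tok)
  if (n < 2L) return(empty_detections())
  is_word <- is_word_token(tok$token)
  rows <- list()
  for (i in 2:n) {
    if (!is_word[i]) next
    lo <- max(1L, i - cfg$window_k)
    for (j in (i - 1L):lo) {
      if (is_word[j] && isTRUE(cfg$comparator(tok$token[i], tok$token[j]))) {
        rows[[length(rows) + 1L]] <- detection_row(
          "repetition", tok$token[j],
          tok$start[j], tok$end[j], tok$start[i], tok$end[i],
          utterance_index = u$index,
          token_index = tok$token_index[j],
          token_index2 = tok$token_index[i])
        break  # nearest previous match only
      }
    }
  }
  if (!length(rows)) return(empty_detections())
  do.call(rbind, rows)
}
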