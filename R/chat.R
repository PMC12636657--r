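# Sentinel tokens that survive preprocessing. Everything else in clean_text is
# plain words and punctuation.
SENTINELS <- c("[silence]", "[<event>]", "[inaudible]")

# internal placeholders used while rewriting CHAT codes, restored at the end so
# that preprocessing is idempotent (sentinels are never re-stripped)
.PH_SILENCE <- "\x01"
.PH_EVENT <- "\x02"
.PH_INAUDIBLE <- "\x03"

#' Tokenize cleaned utterance text
#'
#' Splits `clean_text` into tokens with 0-based, half-open character spans.
#' Sentinel tokens (`[silence]`, `[<event>]`, `[inaudible]`) are kept as single
#' tokens; words are runs of letters/apostrophes; any other non-space character
#' is a one-character punctuation token.
#'
#' @param clean_text character scalar produced by [preprocess_utterance()].
#' @return data.frame with columns `token`, `start`, `end` (spans into
#'   `clean_text`, 0-based half-open, strictly increasing, non-overlapping).
#' @export
chat_tokenize <- function(clean_text) {
  stopifnot(is.character(clean_text), length(clean_text) == 1L)
  if (is.na(clean_text) || !nzchar(clean_text)) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  pat <- "\\[silence\\]|\\[<event>\\]|\\[inaudible\\]|[A-Za-z']+|[^\\sA-Za-z']"
  m <- gregexpr(pat, clean_text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(
    token = substring(clean_text, starts + 1L, starts + lens),
    start = starts,
    end = starts + as.integer(lens),
    stringsAsFactors = FALSE
  )
}

is_sentinel_token <- function(token) token %in% SENTINELS

is_word_token <- function(token) grepl("^[A-Za-z']+$", token)

# lexical token: a word that is not a sentinel (sentinels never match the word
# pattern anyway, but be explicit)
is_lexical_token <- function(token) is_word_token(token) & !is_sentinel_token(token)

#' Clean one CHAT main-tier utterance
#'
#' Rewrites CHAT annotation codes into plain text per the preprocessing rules:
#' pause codes `(.)`, `(..)`, `(...)`/`(…)` become `[silence]`; event codes
#' (`&=action`) become `[<event>]`; unintelligible material (`xxx`, `yyy`,
#' `www`) becomes `[inaudible]`; filler prefixes (`&um`, `&-um`) are stripped
#' keeping the word; all other codes (square-bracket codes such as `[/]`,
#' `[*]`, `[+ es]`, angle-bracket retrace groups, parenthesised shortenings)
#' are stripped, keeping underlying words where they exist. Unknown codes are
#' stripped with a warning (class `cogspeech_unknown_code`), never an error.
#' The function is idempotent: applying it to its own output is a no-op.
#'
#' @param raw_text one main-tier utterance body (text after the `*SPK:` marker).
#' @return list with `clean_text` (character) and `tokens` (see
#'   [chat_tokenize()]).
#' @export
preprocess_utterance <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  x <- if (is.na(raw_text)) "" else raw_text

  # protect sentinels already present (idempotency under re-processing)
  x <- gsub("[silence]", .PH_SILENCE, x, fixed = TRUE)
  x <- gsub("[<event>]", .PH_EVENT, x, fixed = TRUE)
  x <- gsub("[inaudible]", .PH_INAUDIBLE, x, fixed = TRUE)

  # square-bracket codes: known ones are stripped silently, anything else is
  # stripped with a warning
  brackets <- regmatches(x, gregexpr("\\[[^][]*\\]", x))[[1]]
  if (length(brackets)) {
    known <- grepl("^\\[(/{1,2}|\\*[^]]*|\\+ (es|cir)|=![^]]*)\\]$", brackets)
    if (any(!known)) {
      warning(warningCondition(
        sprintf("stripping unknown CHAT code(s): %s",
                paste(unique(brackets[!known]), collapse = " ")),
        class = "cogspeech_unknown_code"))
    }
    x <- gsub("\\[[^][]*\\]", " ", x)
  }
  # angle-bracket groups mark retraced material: keep the words
  x <- gsub("[<>]", " ", x)

  # pause codes (both ASCII and ellipsis-glyph forms)
  x <- gsub("(...)", paste0(" ", .PH_SILENCE, " "), x, fixed = TRUE)
  x <- gsub("(..)",  paste0(" ", .PH_SILENCE, " "), x, fixed = TRUE)
  x <- gsub("(.)",   paste0(" ", .PH_SILENCE, " "), x, fixed = TRUE)
  x <- gsub("(…)", paste0(" ", .PH_SILENCE, " "), x, fixed = TRUE)

  # event codes, unintelligible material, filler prefixes
  x <- gsub("&=[A-Za-z_:]+", paste0(" ", .PH_EVENT, " "), x)
  x <- gsub("\\b(xxx|yyy|www)\\b", paste0(" ", .PH_INAUDIBLE, " "), x)
  x <- gsub("&-?([A-Za-z']+)", " \\1 ", x)

  # parenthesised shortenings, e.g. "(be)cause" -> "because"
  x <- gsub("[()]", "", x)

  # leftover code-like tokens (e.g. "+//.", "+...") -> strip with warning
  plus <- regmatches(x, gregexpr("(^|\\s)\\+\\S*", x))[[1]]
  if (length(plus)) {
    warning(warningCondition(
      sprintf("stripping unknown CHAT code(s): %s",
              paste(trimws(unique(plus)), collapse = " ")),
      class = "cogspeech_unknown_code"))
    x <- gsub("(^|\\s)\\+\\S*", " ", x)
  }

  # normalize whitespace
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)

  # restore sentinels
  x <- gsub(.PH_SILENCE, "[silence]", x, fixed = TRUE)
  x <- gsub(.PH_EVENT, "[<event>]", x, fixed = TRUE)
  x <- gsub(.PH_INAUDIBLE, "[inaudible]", x, fixed = TRUE)

  list(clean_text = x, tokens = chat_tokenize(x))
}

#' Derive per-utterance indicator labels from CHAT codes
#'
#' Each flag is read straight off the raw CHAT line, never off the cleaned
#' text: `filler` if any word carries the filler prefix `&` (the event prefix
#' `&=` does not count); `repetition` if the retracing code `[/]` is present;
#' `substitution` if a word-level error code `[*]` (any subtype, e.g. `[* s]`,
#' `[* n]`) is present; `vague` if the empty-speech `[+ es]` or circumlocution
#' `[+ cir]` postcode is present; `delay` if any pause code `(.)`, `(..)`,
#' `(...)`/`(…)` is present.
#'
#' @param raw_text one main-tier utterance body with its original CHAT codes.
#' @return named logical vector: `filler`, `repetition`, `substitution`,
#'   `vague`, `delay`.
#' @export
derive_labels <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  x <- if (is.na(raw_text)) "" else raw_text
  c(
    filler = grepl("(^|[^A-Za-z&])&(-?[A-Za-z'])", x),
    repetition = grepl("[/]", x, fixed = TRUE),
    substitution = grepl("\\[\\*[^]]*\\]", x),
    vague = grepl("[+ es]", x, fixed = TRUE) || grepl("[+ cir]", x, fixed = TRUE),
    delay = grepl("(.)", x, fixed = TRUE) || grepl("(..)", x, fixed = TRUE) ||
      grepl("(...)", x, fixed = TRUE) || grepl("(…)", x, fixed = TRUE)
  )
}

#' Parse a CHAT (.cha) document
#'
#' Reads header `@`-lines, main `*SPK:` tiers and dependent `%`-tiers.
#' Each main tier becomes one utterance (tab-indented continuation lines are
#' joined); dependent tiers and headers are retained as metadata. Cleaning and
#' token spans are computed with [preprocess_utterance()].
#'
#' @param document path to a `.cha` file, a connection, or a character vector
#'   of lines.
#' @param patient_speaker tier code of the patient (default `"PAR"`,
#'   the DementiaBank convention).
#' @param subject_id optional subject identifier; defaults to the third field
#'   of the patient's `@ID` header, then `@PID`, then the file name.
#' @return object of class `chat_transcript`: list with `subject_id`,
#'   `patient_speaker`, `headers` and `utterances` (each utterance a list with
#'   `index`, `speaker`, `raw_text`, `clean_text`, `tokens`, `labels`,
#'   `tiers`).
#' @export
parse_chat <- function(document, patient_speaker = "PAR", subject_id = NULL) {
  default_id <- "unknown"
  if (is.character(document) && length(document) == 1L &&
      !grepl("\n", document) && file.exists(document)) {
    default_id <- tools::file_path_sans_ext(basename(document))
    lines <- readLines(document, encoding = "UTF-8", warn = FALSE)
  } else if (inherits(document, "connection")) {
    lines <- readLines(document, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(document), "\n", fixed = TRUE))
  }

  headers <- character()
  utterances <- list()
  # each record: type ("main"/"dep"), speaker, body
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (cur$type == "main") {
      utterances[[length(utterances) + 1L]] <<- list(
        speaker = cur$speaker, raw_text = trimws(cur$body))
    } else if (cur$type == "dep" && length(utterances)) {
      u <- utterances[[length(utterances)]]
      u$tiers <- c(u$tiers, stats::setNames(list(trimws(cur$body)), cur$speaker))
      utterances[[length(utterances)]] <<- u
    }
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    first <- substr(line, 1L, 1L)
    if (first == "\t" || first == " ") {
      # continuation of the previous tier
      if (is.null(cur)) {
        warning(sprintf("line %d: continuation with no open tier; skipped", i))
        next
      }
      cur$body <- paste(cur$body, trimws(line))
    } else if (first == "@") {
      flush()
      headers <- c(headers, line)
    } else if (first == "*") {
      flush()
      colon <- regexpr(":", line, fixed = TRUE)
      if (colon == -1L) {
        stop(sprintf("malformed speaker tier at line %d (no colon): %s",
                     i, line), call. = FALSE)
      }
      cur <- list(type = "main",
                  speaker = substr(line, 2L, colon - 1L),
                  body = substr(line, colon + 1L, nchar(line)))
    } else if (first == "%") {
      flush()
      colon <- regexpr(":", line, fixed = TRUE)
      if (colon == -1L) {
        stop(sprintf("malformed dependent tier at line %d (no colon): %s",
                     i, line), call. = FALSE)
      }
      cur <- list(type = "dep",
                  speaker = substr(line, 1L, colon - 1L),
                  body = substr(line, colon + 1L, nchar(line)))
    } else {
      warning(sprintf("line %d: unrecognized line skipped: %s", i, line))
    }
  }
  flush()

  if (is.null(subject_id)) {
    id_hdr <- headers[startsWith(headers, "@ID")]
    pid_hdr <- headers[startsWith(headers, "@PID")]
    subject_id <- default_id
    for (h in id_hdr) {
      fields <- strsplit(sub("^@ID:\\s*", "", h), "|", fixed = TRUE)[[1]]
      if (length(fields) >= 3 && grepl(patient_speaker, h, fixed = TRUE)) {
        subject_id <- trimws(fields[3]); break
      }
    }
    if (identical(subject_id, default_id) && length(pid_hdr)) {
      subject_id <- trimws(sub("^@PID:\\s*", "", pid_hdr[[1]]))
    }
  }

  utts <- vector("list", length(utterances))
  for (k in seq_along(utterances)) {
    u <- utterances[[k]]
    pp <- preprocess_utterance(u$raw_text)
    utts[[k]] <- list(
      index = k - 1L,
      speaker = u$speaker,
      raw_text = u$raw_text,
      clean_text = pp$clean_text,
      tokens = pp$tokens,
      labels = derive_labels(u$raw_text),
      tiers = u$tiers
    )
  }

  structure(
    list(subject_id = subject_id, patient_speaker = patient_speaker,
         headers = headers, utterances = utts),
    class = "chat_transcript"
  )
}

#' @export
print.chat_transcript <- function(x, ...) {
  n_pat <- sum(vapply(x$utterances, function(u)
    identical(u$speaker, x$patient_speaker), logical(1)))
  cat(sprintf("<chat_transcript> subject %s: %d utterances (%d by %s)\n",
              x$subject_id, length(x$utterances), n_pat, x$patient_speaker))
  invisible(x)
}

#' Patient utterances of a transcript
#' @param t a `chat_transcript`.
#' @return list of utterances spoken by `t$patient_speaker`.
#' @export
patient_utterances <- function(t) {
  stopifnot(inherits(t, "chat_transcript"))
  Filter(function(u) identical(u$speaker, t$patient_speaker), t$utterances)
}

#' Write a cleaned-transcript JSON representation
#'
#' @param t a `chat_transcript`.
#' @param path output file.
#' @export
write_transcript_json <- function(t, path) {
  stopifnot(inherits(t, "chat_transcript"))
  out <- list(
    subject_id = t$subject_id,
    patient_speaker = t$patient_speaker,
    utterances = lapply(t$utterances, function(u) list(
      index = u$index, speaker = u$speaker, raw = u$raw_text,
      clean = u$clean_text, labels = as.list(u$labels)
    ))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Age-balanced stratified subject split
#'
#' Generates `n_candidates` random splits stratified on sex and diagnostic
#' label at the requested fraction, and returns the candidate whose absolute
#' difference in mean age between the two partitions is smallest.
#'
#' @param subjects data.frame with columns `id`, `age`, `sex`, `label`.
#' @param fraction proportion of each stratum assigned to partition A
#'   (default 0.7).
#' @param n_candidates number of candidate splits scored (default 100).
#' @param seed integer seed; the search is deterministic given the seed.
#' @param return_all also return every candidate with its age gap (for
#'   auditing the search).
#' @return list with `train` (partition A ids), `dev` (partition B ids),
#'   `age_gap` (the winning absolute mean-age difference) and `candidate`
#'   (index of the winning candidate); with `return_all`, also `candidates`,
#'   a list of all scored candidate splits.
#' @export
make_balanced_split <- function(subjects, fraction = 0.7, n_candidates = 100,
                                seed = 1L, return_all = FALSE) {
  stopifnot(is.data.frame(subjects),
            all(c("id", "age", "sex", "label") %in% names(subjects)),
            n_candidates >= 1, fraction > 0, fraction < 1)
  strata <- interaction(subjects$sex, subjects$label, drop = TRUE)
  sizes <- table(strata)
  if (any(sizes < 2)) {
    stop("cannot stratify: stratum ", names(sizes)[which(sizes < 2)[1]],
         " has fewer than 2 subjects", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  best <- NULL
  all_cands <- if (return_all) vector("list", n_candidates) else NULL
  for (cand in seq_len(n_candidates)) {
    in_a <- logical(nrow(subjects))
    for (s in levels(strata)) {
      idx <- which(strata == s)
      n_a <- round(fraction * length(idx))
      n_a <- max(1L, min(length(idx) - 1L, n_a))
      in_a[sample(idx, n_a)] <- TRUE
    }
    gap <- abs(mean(subjects$age[in_a]) - mean(subjects$age[!in_a]))
    if (return_all) {
      all_cands[[cand]] <- list(train = subjects$id[in_a],
                                dev = subjects$id[!in_a], age_gap = gap)
    }
    if (is.null(best) || gap < best$age_gap) {
      best <- list(train = subjects$id[in_a], dev = subjects$id[!in_a],
                   age_gap = gap, candidate = cand)
    }
  }
  if (return_all) best$candidates <- all_cands
  best
}
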