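# Stage 2: aggregate detections and silences into the interpretable summary
# feature vector for one subject. All rates are per patient word; silence
# statistics are normalized by the patient's speaking time. Undefined
# statistics (no event pairs, zero denominators) are encoded as 0 with a
# companion missing-mask so the downstream scaler always sees numbers.

FEATURE_NAMES <- c(
  "filler_rate", "ifd_mean", "ifd_std",
  "repetition_rate",
  "rep_rate_noun", "rep_rate_verb", "rep_rate_adjective", "rep_rate_adverb",
  "rep_rate_pronoun", "rep_rate_determiner",
  "substitution_rate", "ised_mean", "ised_std",
  "vague_terms_rate", "vague_utterance_ratio",
  "silence_duration_norm", "silence_count_norm", "long_short_silence_ratio"
)

#' Feature column names, in canonical order
#' @export
feature_names <- function() FEATURE_NAMES

#' Patient speech statistics
#'
#' @param t a `chat_transcript`.
#' @param speaking_time_ms the patient's total speaking time in ms. When
#'   diarized timing is unavailable, compute it as total audio duration minus
#'   total detected silence (the fallback is flagged in the diagnostic
#'   profile).
#' @return list with `total_words` (patient lexical tokens), `total_utterances`
#'   (patient utterances) and `speaking_time_ms`.
#' @export
patient_speech_stats <- function(t, speaking_time_ms = NA_real_) {
  stopifnot(inherits(t, "chat_transcript"))
  pats <- patient_utterances(t)
  total_words <- sum(vapply(pats, function(u)
    sum(is_lexical_token(u$tokens$token)), integer(1)))
  list(total_words = total_words, total_utterances = length(pats),
       speaking_time_ms = speaking_time_ms)
}

#' Detection count normalized by patient word count
#'
#' @param count number of detections.
#' @param stats a [patient_speech_stats()] list.
#' @return list with `value` and `missing` (TRUE when total_words is 0, the
#'   undefined-feature sentinel).
#' @export
rate <- function(count, stats) {
  if (is.null(stats$total_words) || stats$total_words <= 0) {
    return(list(value = 0, missing = TRUE))
  }
  list(value = count / stats$total_words, missing = FALSE)
}

# lexical-token position (0-based among the utterance's lexical tokens) of a
# detection, located by its span start
lexical_position <- function(det_start, utterance) {
  starts <- utterance$tokens$start[is_lexical_token(utterance$tokens$token)]
  pos <- match(det_start, starts)
  if (is.na(pos)) {
    # span starting inside a token (should not happen for token-aligned
    # detectors); fall back to the last token starting at or before it
    pos <- max(which(starts <= det_start), 1L)
  }
  pos - 1L
}

#' Inter-detection distances (pooled mean and population SD)
#'
#' For every utterance with at least two detections of the given type, counts
#' the lexical words strictly between each consecutive detection pair; gaps
#' are pooled across utterances and summarized by mean and population standard
#' deviation (divide by n). Utterances with fewer than two detections
#' contribute no gaps.
#'
#' @param detections detection data.frame (with `utterance_index` and `start`).
#' @param t the `chat_transcript` the detections refer to.
#' @return list with `mean`, `std`, `missing` (TRUE when no gaps exist).
#' @export
inter_detection_distances <- function(detections, t) {
  utts <- stats::setNames(t$utterances,
                          vapply(t$utterances, function(u) as.character(u$index),
                                 character(1)))
  gaps <- numeric()
  if (nrow(detections)) {
    for (ui in unique(detections$utterance_index)) {
      d <- detections[detections$utterance_index == ui, , drop = FALSE]
      if (nrow(d) < 2) next
      u <- utts[[as.character(ui)]]
      pos <- sort(vapply(d$start, lexical_position, numeric(1), utterance = u))
      gaps <- c(gaps, diff(pos) - 1)
    }
  }
  if (!length(gaps)) return(list(mean = 0, std = 0, missing = TRUE))
  m <- mean(gaps)
  list(mean = m, std = sqrt(mean((gaps - m)^2)), missing = FALSE)
}

#' Per-part-of-speech repetition rates
#'
#' Counts repetitions whose repeated word is tagged noun, verb, adjective,
#' adverb, pronoun, or determiner, each divided by the patient's total word
#' count. (The determiner rate is computed here and typically dropped by the
#' model stage as zero-variance.)
#'
#' @param repetitions repetition detections.
#' @param t the transcript.
#' @param tagger a tagger function `(tokens, index) -> tag`, e.g.
#'   [lexicon_tagger()].
#' @param stats [patient_speech_stats()].
#' @return named list of `rate()` results for the six tags.
#' @export
pos_repetition_rates <- function(repetitions, t, tagger, stats) {
  tags <- c("noun", "verb", "adjective", "adverb", "pronoun", "determiner")
  counts <- stats::setNames(numeric(length(tags)), tags)
  if (nrow(repetitions)) {
    utts <- stats::setNames(t$utterances,
                            vapply(t$utterances, function(u) as.character(u$index),
                                   character(1)))
    for (r in seq_len(nrow(repetitions))) {
      u <- utts[[as.character(repetitions$utterance_index[r])]]
      toks <- u$tokens$token
      idx <- which(u$tokens$start == repetitions$start[r])[1]
      if (is.na(idx)) next
      tg <- tagger(toks, idx)
      if (tg %in% tags) counts[tg] <- counts[tg] + 1
    }
  }
  lapply(as.list(counts), rate, stats = stats)
}

#' Proportion of patient utterances flagged as vague
#'
#' @param vague_detections vague detections.
#' @param stats [patient_speech_stats()] (needs `total_utterances > 0`).
#' @export
vague_utterance_ratio <- function(vague_detections, stats) {
  stopifnot(stats$total_utterances > 0)
  n <- length(unique(vague_detections$utterance_index[
    !is.na(vague_detections$utterance_index)]))
  list(value = n / stats$total_utterances, missing = FALSE)
}

#' Silence summary features
#'
#' `duration_norm` = total silent ms / speaking time; `count_norm` = segment
#' count / speaking time; `long_short_ratio` = summed duration of segments
#' strictly longer than `long_cutoff_ms` over summed duration of segments at
#' or below it (sentinel when the short-silence duration is zero).
#'
#' @param silences data.frame of segments (`start_ms`, `end_ms`).
#' @param stats [patient_speech_stats()] with `speaking_time_ms > 0`.
#' @param long_cutoff_ms long/short cutoff (default 300 ms).
#' @export
silence_features <- function(silences, stats, long_cutoff_ms = 300) {
  if (is.null(stats$speaking_time_ms) || is.na(stats$speaking_time_ms) ||
      stats$speaking_time_ms <= 0) {
    stop("speaking_time_ms must be positive for silence normalization",
         call. = FALSE)
  }
  dur <- silences$end_ms - silences$start_ms
  long_sum <- sum(dur[dur > long_cutoff_ms])
  short_sum <- sum(dur[dur <= long_cutoff_ms])
  list(
    duration_norm = list(value = sum(dur) / stats$speaking_time_ms,
                         missing = FALSE),
    count_norm = list(value = nrow(silences) / stats$speaking_time_ms,
                      missing = FALSE),
    long_short_ratio = if (short_sum > 0) {
      list(value = long_sum / short_sum, missing = FALSE)
    } else {
      list(value = 0, missing = TRUE)
    }
  )
}

#' Assemble the full summary feature vector for one subject
#'
#' @param t a `chat_transcript`.
#' @param detections detection data.frame covering all indicator types
#'   (column `type` in filler/repetition/substitution/vague).
#' @param silences silence segments data.frame.
#' @param stats [patient_speech_stats()] (must have `total_words > 0` and a
#'   positive `speaking_time_ms`).
#' @param tagger part-of-speech provider (default [lexicon_tagger()]).
#' @param long_cutoff_ms long/short silence cutoff (default 300 ms).
#' @return object of class `feature_vector`: list with `values` (named numeric
#'   vector over [feature_names()]), `missing` (named logical mask) and
#'   `stats`.
#' @export
build_feature_vector <- function(t, detections, silences, stats,
                                 tagger = lexicon_tagger(),
                                 long_cutoff_ms = 300) {
  stopifnot(inherits(t, "chat_transcript"))
  if (stats$total_words <= 0) {
    stop("empty patient speech: no words to normalize by", call. = FALSE)
  }
  by_type <- function(tp) detections[!is.na(detections$type) &
                                       detections$type == tp, , drop = FALSE]
  fil <- by_type("filler"); rep_ <- by_type("repetition")
  sub <- by_type("substitution"); vag <- by_type("vague")

  vals <- stats::setNames(numeric(length(FEATURE_NAMES)), FEATURE_NAMES)
  miss <- stats::setNames(logical(length(FEATURE_NAMES)), FEATURE_NAMES)
  put <- function(name, x) {
    vals[name] <<- x$value; miss[name] <<- x$missing
  }

  put("filler_rate", rate(nrow(fil), stats))
  ifd <- inter_detection_distances(fil, t)
  put("ifd_mean", list(value = ifd$mean, missing = ifd$missing))
  put("ifd_std", list(value = ifd$std, missing = ifd$missing))

  put("repetition_rate", rate(nrow(rep_), stats))
  posr <- pos_repetition_rates(rep_, t, tagger, stats)
  put("rep_rate_noun", posr$noun); put("rep_rate_verb", posr$verb)
  put("rep_rate_adjective", posr$adjective)
  put("rep_rate_adverb", posr$adverb)
  put("rep_rate_pronoun", posr$pronoun)
  put("rep_rate_determiner", posr$determiner)

  put("substitution_rate", rate(nrow(sub), stats))
  ised <- inter_detection_distances(sub, t)
  put("ised_mean", list(value = ised$mean, missing = ised$missing))
  put("ised_std", list(value = ised$std, missing = ised$missing))

  put("vague_terms_rate", rate(nrow(vag), stats))
  put("vague_utterance_ratio", vague_utterance_ratio(vag, stats))

  sil <- silence_features(silences, stats, long_cutoff_ms)
  put("silence_duration_norm", sil$duration_norm)
  put("silence_count_norm", sil$count_norm)
  put("long_short_silence_ratio", sil$long_short_ratio)

  structure(list(values = vals, missing = miss, stats = stats,
                 subject_id = t$subject_id),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, digits = 4, ...) {
  cat(sprintf("<feature_vector> subject %s (%d words, %d utterances)\n",
              x$subject_id, x$stats$total_words, x$stats$total_utterances))
  v <- format(round(x$values, digits))
  v[x$missing] <- paste0(v[x$missing], " (undefined)")
  for (n in names(x$values)) cat(sprintf("  %-26s %s\n", n, v[[n]]))
  invisible(x)
}

#' Stack feature vectors into a matrix
#'
#' @param fvs list of `feature_vector` objects.
#' @return numeric matrix (subjects x features) with subject ids as row names;
#'   the combined missing-mask is attached as attribute `"missing"`.
#' @export
feature_matrix <- function(fvs) {
  stopifnot(length(fvs) > 0)
  m <- do.call(rbind, lapply(fvs, function(f) f$values))
  rownames(m) <- vapply(fvs, function(f) f$subject_id, character(1))
  attr(m, "missing") <- do.call(rbind, lapply(fvs, function(f) f$missing))
  m
}

#' Write feature vectors as CSV (one row per subject, canonical column order)
#' @param fvs list of `feature_vector` objects.
#' @param path output file.
#' @export
write_features_csv <- function(fvs, path) {
  m <- feature_matrix(fvs)
  df <- data.frame(subject_id = rownames(m), m, row.names = NULL,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
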