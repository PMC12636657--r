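# Shared fixtures and independent oracles, built in code at test time.

# utterance object from already-clean text (as preprocess_utterance would emit)
make_utterance <- function(clean_text, index = 0L, speaker = "PAR") {
  list(index = index, speaker = speaker, raw_text = clean_text,
       clean_text = clean_text, tokens = chat_tokenize(clean_text),
       labels = derive_labels(clean_text), tiers = NULL)
}

# transcript from a character vector of clean patient utterance texts
make_transcript <- function(texts, subject_id = "fixture") {
  utts <- lapply(seq_along(texts), function(i)
    make_utterance(texts[[i]], index = i - 1L))
  structure(list(subject_id = subject_id, patient_speaker = "PAR",
                 headers = character(), utterances = utts),
            class = "chat_transcript")
}

# Independent brute-force repetition oracle: for every token i (words only),
# find all previous positions j with i - j <= K whose token matches
# case-insensitively, keep the nearest, skipping sentinels from the stream and
# letting punctuation occupy window slots without matching.
oracle_repetitions <- function(tokens, K) {
  keep <- !(tokens %in% c("[silence]", "[<event>]", "[inaudible]"))
  stream <- tokens[keep]
  is_word <- grepl("^[A-Za-z']+$", stream)
  hits <- list()
  n <- length(stream)
  if (n >= 2) {
    for (i in 2:n) {
      if (!is_word[i]) next
      matches <- integer()
      for (j in seq_len(i - 1)) {
        if (i - j <= K && is_word[j] &&
            tolower(stream[i]) == tolower(stream[j])) {
          matches <- c(matches, j)
        }
      }
      if (length(matches)) {
        hits[[length(hits) + 1L]] <- c(prev = max(matches), cur = i)
      }
    }
  }
  hits
}

# Independent n-gram scan counting keyword occurrences (no overlap handling:
# used on fixtures without overlapping terms)
oracle_keyword_count <- function(tokens, terms) {
  keep <- !(tokens %in% c("[silence]", "[<event>]", "[inaudible]"))
  low <- tolower(tokens[keep])
  total <- 0L
  for (term in terms) {
    tt <- strsplit(term, "\\s+")[[1]]
    L <- length(tt)
    if (L > length(low)) next
    for (i in seq_len(length(low) - L + 1L)) {
      if (all(low[i:(i + L - 1L)] == tt)) total <- total + 1L
    }
  }
  total
}

# population standard deviation, the convention used by the feature layer
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# small model configuration usable at toy sample sizes (the clinical default
# of 12 samples per leaf needs larger folds)
toy_model_config <- function(...) {
  model_config(min_samples_per_leaf = 3, feature_fraction = 1,
               n_estimators = 500, ...)
}

# Canonical hand-worked fixture used for exact feature checks.
# Patient utterances (clean text), 20 lexical words in total:
#   U0 "um the boy um falls ."        fillers at lexical positions 0 and 3
#   U1 "boy boy takes the jar ."      one repetition of "boy" (noun)
#   U2 "she took the thing and the stuff ."  vague: thing, stuff;
#                                     hand substitutions at positions 1 and 3
#   U3 "the water overflows ."        clean
canonical_fixture <- function() {
  t <- make_transcript(c("um the boy um falls .",
                         "boy boy takes the jar .",
                         "she took the thing and the stuff .",
                         "the water overflows ."))
  span_of <- function(ui, word, occurrence = 1L) {
    tok <- t$utterances[[ui + 1L]]$tokens
    hit <- which(tok$token == word)[occurrence]
    c(tok$start[hit], tok$end[hit])
  }
  det <- rbind(
    { s <- span_of(0, "um", 1); detection_row_test("filler", "um", s, 0L) },
    { s <- span_of(0, "um", 2); detection_row_test("filler", "um", s, 0L) },
    { s <- span_of(1, "boy", 1); d <- detection_row_test("repetition", "boy", s, 1L)
      s2 <- span_of(1, "boy", 2); d$start2 <- s2[1]; d$end2 <- s2[2]; d },
    { s <- span_of(2, "took", 1); detection_row_test("substitution", "took", s, 2L) },
    { s <- span_of(2, "thing", 1); detection_row_test("substitution", "thing", s, 2L) },
    { s <- span_of(2, "thing", 1); detection_row_test("vague", "thing", s, 2L) },
    { s <- span_of(2, "stuff", 1); detection_row_test("vague", "stuff", s, 2L) }
  )
  silences <- data.frame(start_ms = c(0, 1000), end_ms = c(400, 1100))
  list(t = t, detections = det, silences = silences,
       stats = patient_speech_stats(t, speaking_time_ms = 10000))
}

detection_row_test <- function(type, text, span, ui) {
  data.frame(type = type, text = text, start = span[1], end = span[2],
             start2 = NA_real_, end2 = NA_real_, utterance_index = ui,
             token_index = NA_integer_, token_index2 = NA_integer_,
             justification = NA_character_, stringsAsFactors = FALSE)
}

empty_detections_test <- function() {
  detection_row_test("filler", "x", c(0, 1), 0L)[0, ]
}

hand_expected <- c(
  filler_rate = 2 / 20, ifd_mean = 2, ifd_std = 0,
  repetition_rate = 1 / 20,
  rep_rate_noun = 1 / 20, rep_rate_verb = 0, rep_rate_adjective = 0,
  rep_rate_adverb = 0, rep_rate_pronoun = 0, rep_rate_determiner = 0,
  substitution_rate = 2 / 20, ised_mean = 1, ised_std = 0,
  vague_terms_rate = 2 / 20, vague_utterance_ratio = 1 / 4,
  silence_duration_norm = 500 / 10000, silence_count_norm = 2 / 10000,
  long_short_silence_ratio = 400 / 100)

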