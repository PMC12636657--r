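# Substitution errors are contextually inappropriate words. The detector masks
# each patient word, asks a masked-language-model backend for the predictive
# distribution at that position, summarizes the distribution's shape with two
# [0,1] metrics (normalized entropy, top-k concentration), fuses them, and
# flags words whose fusion score exceeds a per-transcript percentile.

#' Substitution-detector configuration
#'
#' @param top_k number of top guesses pooled by the concentration ratio
#'   (default 5).
#' @param entropy_weight weight of normalized entropy in the fusion score,
#'   in `[0, 1]` (default 0.5).
#' @param percentile flag threshold percentile in `(0, 100)` (default 90, the
#'   F1-optimal threshold).
#' @param context `"transcript"` (default) scores each word against the whole
#'   patient token sequence; `"utterance"` restricts context to the utterance.
#' @export
substitution_config <- function(top_k = 5, entropy_weight = 0.5,
                                percentile = 90, context = "transcript") {
  stopifnot(top_k >= 1, entropy_weight >= 0, entropy_weight <= 1,
            percentile > 0, percentile < 100,
            context %in% c("transcript", "utterance"))
  structure(list(top_k = as.integer(top_k), entropy_weight = entropy_weight,
                 percentile = percentile, context = context),
            class = "substitution_config")
}

validate_distribution <- function(p) {
  if (!is.numeric(p) || length(p) < 2 || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-6) {
    stop("invalid probability distribution (must be non-negative, length >= 2, sum to 1)",
         call. = FALSE)
  }
  invisible(p)
}

#' Normalized Shannon entropy of a masked prediction
#'
#' `H(p) / log(V)` with the convention `0 * log(0) = 0`: 1 for a uniform
#' distribution (maximal uncertainty), 0 for a point mass. Invariant under
#' permutation of the vocabulary.
#'
#' @param p probability vector over a vocabulary of size `V >= 2`.
#' @return value in `[0, 1]`.
#' @export
normalized_entropy <- function(p) {
  validate_distribution(p)
  pos <- p[p > 0]
  h <- -sum(pos * log(pos))
  min(1, max(0, h / log(length(p))))
}

#' Top-k concentration ratio of a masked prediction
#'
#' Sum of the `top_k` largest probabilities: how much mass the model puts on
#' its best guesses (1 = fully confident point mass, `k/V` for uniform).
#'
#' @param p probability vector.
#' @param top_k number of top outcomes pooled (`<= length(p)`).
#' @return value in `[0, 1]`.
#' @export
concentration_ratio <- function(p, top_k = 5) {
  validate_distribution(p)
  stopifnot(top_k >= 1, top_k <= length(p))
  min(1, sum(sort(p, decreasing = TRUE)[seq_len(top_k)]))
}

#' Fusion of the two distribution-shape scores
#'
#' `w * NE + (1 - w) * (1 - CR)`: higher means more anomalous (high
#' uncertainty, low confidence). Both operands already live in `[0, 1]`.
#'
#' @param ne normalized entropy.
#' @param cr concentration ratio.
#' @param entropy_weight weight `w` in `[0, 1]`.
#' @return value in `[0, 1]`.
#' @export
fusion_score <- function(ne, cr, entropy_weight = 0.5) {
  stopifnot(ne >= 0, ne <= 1, cr >= 0, cr <= 1,
            entropy_weight >= 0, entropy_weight <= 1)
  entropy_weight * ne + (1 - entropy_weight) * (1 - cr)
}

# Percentile convention used for the flag threshold: linear interpolation of
# order statistics at the Weibull plotting position (quantile type 6). With n
# distinct scores this flags exactly n - ceiling(n * p / 100) words.
flag_quantile <- function(x, percentile) {
  stats::quantile(x, probs = percentile / 100, type = 6, names = FALSE)
}

#' Deterministic vocabulary stub backend
#'
#' Returns a backend closure for [detect_substitutions()]: a point mass on the
#' masked word when it belongs to `vocab` (perfectly predictable) and a uniform
#' distribution otherwise (maximally surprising). Useful for tests and for the
#' synthetic pipeline, where planted error words are out-of-vocabulary.
#'
#' @param vocab character vector of known (lowercase) words.
#' @return function `(tokens, mask_index) -> probability vector`.
#' @export
mlm_backend_stub <- function(vocab) {
  vocab <- unique(tolower(vocab))
  stopifnot(length(vocab) >= 1)
  v_size <- length(vocab) + 1L  # one extra slot for out-of-vocabulary mass
  function(tokens, mask_index) {
    word <- tolower(tokens[[mask_index]])
    idx <- match(word, vocab)
    if (is.na(idx)) return(rep(1 / v_size, v_size))
    p <- rep(0, v_size)
    p[idx] <- 1
    p
  }
}

#' Corpus unigram-frequency backend
#'
#' A simple distributional backend: the predictive distribution at any masked
#' position is proportional to leave-one-out unigram counts over the corpus
#' vocabulary (plus add-one smoothing over an out-of-vocabulary slot). Words
#' seen only once in the corpus receive flatter, lower-confidence predictions.
#'
#' @param corpus_tokens character vector of corpus tokens defining the
#'   vocabulary and counts.
#' @return function `(tokens, mask_index) -> probability vector`.
#' @export
mlm_backend_frequency <- function(corpus_tokens) {
  corpus_tokens <- tolower(corpus_tokens)
  vocab <- sort(unique(corpus_tokens))
  counts <- table(factor(corpus_tokens, levels = vocab))
  function(tokens, mask_index) {
    word <- tolower(tokens[[mask_index]])
    cnt <- as.numeric(counts)
    idx <- match(word, vocab)
    if (!is.na(idx)) cnt[idx] <- max(0, cnt[idx] - 1)  # leave one out
    cnt <- c(cnt, 0) + 1  # smoothing; last slot = out-of-vocabulary
    cnt / sum(cnt)
  }
}

#' Score every patient word with the masked-language-model scheme
#'
#' @param t a `chat_transcript`.
#' @param backend function `(tokens, mask_index) -> probability vector`.
#' @param cfg a [substitution_config()].
#' @return data.frame of word scores: `utterance_index`, `token_index`,
#'   `token`, `start`, `end`, `normalized_entropy`, `concentration_ratio`,
#'   `fusion`.
#' @export
score_substitutions <- function(t, backend, cfg = substitution_config()) {
  stopifnot(inherits(t, "chat_transcript"), is.function(backend),
            inherits(cfg, "substitution_config"))
  pats <- patient_utterances(t)
  rows <- list()
  for (u in pats) {
    tok <- u$tokens
    lex <- which(is_lexical_token(tok$token))
    for (i in lex) {
      rows[[length(rows) + 1L]] <- data.frame(
        utterance_index = u$index, token_index = i - 1L,
        token = tok$token[i], start = tok$start[i], end = tok$end[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(utterance_index = integer(), token_index = integer(),
                      token = character(), start = numeric(), end = numeric(),
                      normalized_entropy = numeric(),
                      concentration_ratio = numeric(), fusion = numeric()))
  }
  scores <- do.call(rbind, rows)

  utt_of <- scores$utterance_index
  all_tokens <- scores$token
  ne <- cr <- numeric(nrow(scores))
  for (r in seq_len(nrow(scores))) {
    if (cfg$context == "transcript") {
      ctx <- all_tokens
      mask_at <- r
    } else {
      sel <- which(utt_of == utt_of[r])
      ctx <- all_tokens[sel]
      mask_at <- match(r, sel)
    }
    p <- backend(ctx, mask_at)
    validate_distribution(p)
    ne[r] <- normalized_entropy(p)
    cr[r] <- concentration_ratio(p, min(cfg$top_k, length(p)))
  }
  scores$normalized_entropy <- ne
  scores$concentration_ratio <- cr
  scores$fusion <- cfg$entropy_weight * ne + (1 - cfg$entropy_weight) * (1 - cr)
  scores
}

#' Detect substitution errors in a transcript
#'
#' Flags every scored word whose fusion score strictly exceeds the
#' `cfg$percentile`-th percentile of all fusion scores in the transcript
#' (linear interpolation of order statistics). With fewer than 2 scorable
#' words the percentile is undefined and an empty result is returned with a
#' warning.
#'
#' @inheritParams score_substitutions
#' @return detection data.frame (type `"substitution"`); word scores are
#'   attached as attribute `"scores"`. The `justification` field records the
#'   three scores.
#' @export
detect_substitutions <- function(t, backend, cfg = substitution_config()) {
  scores <- score_substitutions(t, backend, cfg)
  if (nrow(scores) < 2) {
    warning("fewer than 2 scorable words; substitution percentile undefined",
            call. = FALSE)
    out <- empty_detections()
    attr(out, "scores") <- scores
    return(out)
  }
  thr <- flag_quantile(scores$fusion, cfg$percentile)
  flagged <- which(scores$fusion > thr)
  scores$flagged <- seq_len(nrow(scores)) %in% flagged
  if (!length(flagged)) {
    out <- empty_detections()
    attr(out, "scores") <- scores
    return(out)
  }
  rows <- lapply(flagged, function(r) {
    detection_row("substitution", scores$token[r], scores$start[r],
                  scores$end[r],
                  utterance_index = scores$utterance_index[r],
                  token_index = scores$token_index[r],
                  justification = sprintf(
                    "normalized_entropy=%.6f; concentration_ratio=%.6f; fusion=%.6f",
                    scores$normalized_entropy[r],
                    scores$concentration_ratio[r], scores$fusion[r]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$utterance_index, out$start), , drop = FALSE]
  attr(out, "scores") <- scores
  out
}

#' Write word scores as CSV
#' @param scores data.frame from [score_substitutions()] (or the `"scores"`
#'   attribute of [detect_substitutions()]).
#' @param path output file.
#' @param subject_id optional subject column value.
#' @export
write_word_scores_csv <- function(scores, path, subject_id = NA_character_) {
  scores$subject_id <- subject_id
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
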