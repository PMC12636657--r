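# Part-of-speech tagging is a pluggable provider: any function
# (tokens, index) -> coarse tag in {"noun","verb","adjective","adverb",
# "pronoun","determiner","other"}. The default is a deterministic lexicon
# tagger so that expected feature values are exact in tests.

#' Build a lexicon-based part-of-speech tagger
#'
#' @param lexicon named character vector mapping lowercase words to coarse
#'   tags; words not in the lexicon tag as `"other"`.
#' @return function `(tokens, index) -> tag`.
#' @export
lexicon_tagger <- function(lexicon = default_pos_lexicon()) {
  stopifnot(is.character(lexicon), !is.null(names(lexicon)))
  function(tokens, index) {
    tag <- unname(lexicon[tolower(tokens[[index]])])
    if (is.na(tag)) "other" else tag
  }
}

#' Default coarse part-of-speech lexicon
#'
#' Covers common English function words and the picture-description vocabulary
#' used by the synthetic generator.
#' @export
default_pos_lexicon <- function() {
  tag <- function(words, t) stats::setNames(rep(t, length(words)), words)
  c(
    tag(c("boy", "girl", "cookie", "cookies", "jar", "sink", "water",
          "mother", "woman", "stool", "window", "plate", "plates", "dish",
          "dishes", "curtain", "curtains", "kitchen", "counter", "floor",
          "cupboard", "garden", "lid", "hand", "shelf"), "noun"),
    tag(c("falls", "fall", "falling", "reaches", "reach", "reaching",
          "takes", "take", "taking", "washes", "wash", "washing",
          "overflows", "overflow", "overflowing", "stands", "stand",
          "standing", "dries", "dry", "drying", "climbs", "climb",
          "climbing", "is", "are", "was", "were", "runs", "run", "running",
          "spills", "spill", "spilling", "sees", "see", "looks", "look"),
        "verb"),
    tag(c("little", "big", "tall", "wet", "full", "empty", "open", "high",
          "small", "busy"), "adjective"),
    tag(c("quickly", "quietly", "almost", "very", "there", "here", "not",
          "away", "over", "down", "up"), "adverb"),
    tag(c("he", "she", "it", "they", "him", "her", "them", "his", "its",
          "their", "who", "that", "this", "these", "those", "i", "you",
          "we"), "pronoun"),
    tag(c("the", "a", "an", "some", "any", "each", "every", "no"),
        "determiner")
  )
}
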