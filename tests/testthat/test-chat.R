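test_that("parse_chat turns main tiers into utterances and keeps metadata", {
  t <- parse_chat(c("@Begin", "*PAR: the boy .", "@End"))
  expect_s3_class(t, "chat_transcript")
  expect_length(t$utterances, 1L)
  expect_equal(t$utterances[[1]]$speaker, "PAR")
  expect_equal(t$utterances[[1]]$index, 0L)
  expect_equal(t$headers, c("@Begin", "@End"))

  # dependent tiers and headers produce no utterances
  t2 <- parse_chat(c("@Begin", "*PAR:\tthe boy .", "%mor:\tdet|the n|boy .",
                     "*INV:\tokay .", "@End"))
  expect_length(t2$utterances, 2L)
  expect_equal(t2$utterances[[1]]$tiers$`%mor`, "det|the n|boy .")

  # continuation lines are joined into the open tier
  t3 <- parse_chat(c("*PAR:\tthe boy", "\tfalls down ."))
  expect_equal(t3$utterances[[1]]$raw_text, "the boy falls down .")
})

test_that("empty documents and malformed tiers are handled per contract", {
  expect_length(parse_chat(character())$utterances, 0L)
  expect_error(parse_chat("*PAR the boy"), "line 1")
})

test_that("pause, event, inaudible and filler codes are rewritten", {
  expect_equal(preprocess_utterance("(.) the boy")$clean_text,
               "[silence] the boy")
  expect_equal(preprocess_utterance("&um the boy")$clean_text, "um the boy")
  expect_equal(preprocess_utterance("")$clean_text, "")
  expect_equal(preprocess_utterance("(..) a (…) b")$clean_text,
               "[silence] a [silence] b")
  expect_equal(preprocess_utterance("&=laughs the boy")$clean_text,
               "[<event>] the boy")
  expect_equal(preprocess_utterance("xxx falls")$clean_text,
               "[inaudible] falls")
  # retracing: repeated material before [/] is kept for the detectors
  expect_equal(preprocess_utterance("the boy [/] boy falls")$clean_text,
               "the boy boy falls")
  expect_equal(preprocess_utterance("<the boy> [/] the boy")$clean_text,
               "the boy the boy")
  # error codes and postcodes are stripped, words kept
  expect_equal(preprocess_utterance("flib [* s] falls [+ es]")$clean_text,
               "flib falls")
  # unknown codes strip with a classed warning, never fail
  expect_warning(out <- preprocess_utterance("the boy [?] falls"),
                 class = "cogspeech_unknown_code")
  expect_equal(out$clean_text, "the boy falls")
})

test_that("token spans are 0-based, half-open, strictly increasing", {
  for (raw in c("&um the (.) boy [/] boy falls [* s] .",
                "she took the thing [+ es] .", "xxx &=coughs (..) over")) {
    pp <- preprocess_utterance(raw)
    tok <- pp$tokens
    expect_true(all(tok$start < tok$end))
    if (nrow(tok) > 1) expect_true(all(diff(tok$start) > 0))
    expect_true(all(tok$end[-nrow(tok)] <= tok$start[-1]))
    # spans index into clean_text
    expect_equal(substr(rep(pp$clean_text, nrow(tok)), tok$start + 1, tok$end),
                 tok$token)
  }
})

test_that("preprocessing is idempotent and never deletes lexical words", {
  set.seed(42)
  words <- c("the", "boy", "falls", "cookie", "jar", "she", "reaches")
  for (i in 1:50) {
    n <- sample(3:8, 1)
    base <- sample(words, n, replace = TRUE)
    raw <- character()
    for (w in base) {
      pre <- sample(c("", "(.) ", "&um ", "&=laughs "), 1,
                    prob = c(0.7, 0.1, 0.1, 0.1))
      post <- sample(c("", " [/] ", " [* s]", " [+ es]"), 1,
                     prob = c(0.7, 0.1, 0.1, 0.1))
      piece <- if (post == " [/] ") paste0(w, post, w) else paste0(w, post)
      raw <- c(raw, paste0(pre, piece))
    }
    raw <- paste(raw, collapse = " ")
    pp <- preprocess_utterance(raw)
    # idempotent
    expect_identical(preprocess_utterance(pp$clean_text)$clean_text,
                     pp$clean_text)
    # multiset of non-sentinel word tokens == words left after code removal
    got <- sort(pp$tokens$token[grepl("^[A-Za-z']+$", pp$tokens$token)])
    manual <- gsub("\\[[^][]*\\]|&=[a-z]+|\\(\\.+\\)", " ", raw)
    manual <- gsub("&", "", manual, fixed = TRUE)
    want <- sort(strsplit(trimws(gsub("\\s+", " ", manual)), " ")[[1]])
    expect_identical(got, want)
  }
})

test_that("indicator labels are derived from the raw CHAT codes", {
  lab <- derive_labels("&um the boy [/] boy (.) falls [* s]")
  expect_identical(lab, c(filler = TRUE, repetition = TRUE,
                          substitution = TRUE, vague = FALSE, delay = TRUE))
  expect_false(any(derive_labels("the boy falls")))
  lab2 <- derive_labels("she um talks [+ es]")
  expect_true(lab2[["vague"]])
  expect_false(lab2[["filler"]])  # "um" without the & prefix is not a filler
  # event prefix &= is not a filler prefix
  expect_false(derive_labels("&=laughs the boy")[["filler"]])
  # subtype forms of the error code count
  expect_true(derive_labels("flib [* n] falls")[["substitution"]])
  expect_true(derive_labels("dog [*] barks")[["substitution"]])
  # both circumlocution and empty-speech postcodes count as vague
  expect_true(derive_labels("the thing [+ cir]")[["vague"]])
  # all three pause codes count as delay, both ellipsis forms
  for (p in c("(.)", "(..)", "(...)", "(…)")) {
    expect_true(derive_labels(paste("a", p, "b"))[["delay"]])
  }
})

test_that("balanced split minimizes the age gap over its candidate set", {
  set.seed(7)
  subjects <- data.frame(
    id = sprintf("s%02d", 1:20),
    age = round(runif(20, 55, 80)),
    sex = rep(c("f", "m"), each = 10),
    label = rep(c(0, 1, 0, 1), each = 5))

  res <- make_balanced_split(subjects, fraction = 0.7, n_candidates = 100,
                             seed = 3, return_all = TRUE)
  gaps <- vapply(res$candidates, function(c) c$age_gap, numeric(1))
  expect_length(gaps, 100)
  expect_equal(res$age_gap, min(gaps))
  expect_true(all(res$age_gap <= gaps))
  # stratification: every sex x label cell split at the fraction
  strata <- interaction(subjects$sex, subjects$label)
  for (s in levels(strata)) {
    ids <- subjects$id[strata == s]
    expect_equal(sum(ids %in% res$train), round(0.7 * length(ids)))
  }
  # deterministic given seed
  res2 <- make_balanced_split(subjects, fraction = 0.7, n_candidates = 100,
                              seed = 3)
  expect_identical(res$train, res2$train)

  # degenerate search returns the single candidate regardless of age
  res1 <- make_balanced_split(subjects, n_candidates = 1, seed = 5,
                              return_all = TRUE)
  expect_equal(res1$candidate, 1L)

  # a stratum smaller than 2 cannot be stratified
  tiny <- data.frame(id = c("a", "b", "c", "d"), age = c(60, 61, 62, 63),
                     sex = c("f", "f", "m", "m"), label = c(0, 1, 0, 1))
  expect_error(make_balanced_split(tiny, seed = 1), "fewer than 2")
})

test_that("transcript JSON writer round-trips ids, speakers and labels", {
  t <- parse_chat(c("@Begin", "@PID:\tsubj42", "*PAR:\t&um the boy .",
                    "*INV:\tokay .", "@End"))
  expect_equal(t$subject_id, "subj42")
  path <- tempfile(fileext = ".json")
  write_transcript_json(t, path)
  back <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(back$subject_id, "subj42")
  expect_length(back$utterances, 2L)
  expect_true(back$utterances[[1]]$labels$filler)
})
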