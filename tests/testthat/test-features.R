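test_that("rates follow the count-over-words definition with a guarded zero", {
  stats <- list(total_words = 30, total_utterances = 5, speaking_time_ms = 1e4)
  expect_equal(rate(3, stats)$value, 0.1)
  expect_equal(rate(0, stats)$value, 0)
  z <- rate(3, list(total_words = 0))
  expect_true(z$missing)
  expect_equal(z$value, 0)
})

test_that("inter-detection distances count intervening lexical words, pooled", {
  fx <- canonical_fixture()
  # detections at lexical positions 0 and 3 -> one gap of 2 words
  fil <- fx$detections[fx$detections$type == "filler", ]
  d <- inter_detection_distances(fil, fx$t)
  expect_equal(d$mean, 2)
  expect_equal(d$std, 0)
  expect_false(d$missing)

  # adjacent detections -> gap 0
  t2 <- make_transcript("um um boy")
  tok <- t2$utterances[[1]]$tokens
  adj <- rbind(detection_row_test("filler", "um", c(tok$start[1], tok$end[1]), 0L),
               detection_row_test("filler", "um", c(tok$start[2], tok$end[2]), 0L))
  expect_equal(inter_detection_distances(adj, t2)$mean, 0)

  # one detection per utterance -> no consecutive pair anywhere -> sentinel
  t3 <- make_transcript(c("um boy", "um jar"))
  one_each <- rbind(
    detection_row_test("filler", "um", c(0, 2), 0L),
    detection_row_test("filler", "um", c(0, 2), 1L))
  expect_true(inter_detection_distances(one_each, t3)$missing)
})

test_that("part-of-speech repetition rates use the repeated word's tag", {
  t <- make_transcript(paste("boy boy takes takes the jar and some more words",
                             "she sees the water spill onto the kitchen floor now"))
  # 20 lexical words; repetitions of "boy" (noun) and "takes" (verb)
  tok <- t$utterances[[1]]$tokens
  reps <- rbind(
    detection_row_test("repetition", "boy", c(tok$start[1], tok$end[1]), 0L),
    detection_row_test("repetition", "takes", c(tok$start[3], tok$end[3]), 0L))
  stats <- patient_speech_stats(t, 1e4)
  expect_equal(stats$total_words, 20)
  r <- pos_repetition_rates(reps, t, lexicon_tagger(), stats)
  expect_equal(r$noun$value, 1 / 20)
  expect_equal(r$verb$value, 1 / 20)
  expect_equal(r$determiner$value, 0)
  # a determiner repetition lands in the determiner bucket
  reps2 <- detection_row_test("repetition", "the", c(tok$start[5], tok$end[5]), 0L)
  r2 <- pos_repetition_rates(reps2, t, lexicon_tagger(), stats)
  expect_equal(r2$determiner$value, 1 / 20)
})

test_that("vague utterance ratio covers the trivial cases", {
  stats <- list(total_utterances = 10, total_words = 50)
  mk <- function(uis) data.frame(utterance_index = uis)
  expect_equal(vague_utterance_ratio(mk(c(0, 0, 3)), stats)$value, 0.2)
  expect_equal(vague_utterance_ratio(mk(integer()), stats)$value, 0)
  expect_equal(vague_utterance_ratio(mk(0:9), stats)$value, 1)
})

test_that("silence features implement the normalized-duration definitions", {
  stats <- list(speaking_time_ms = 10000)
  s <- data.frame(start_ms = c(0, 1000), end_ms = c(400, 1100))
  f <- silence_features(s, stats)
  expect_equal(f$duration_norm$value, 0.05)
  expect_equal(f$count_norm$value, 2e-4)
  expect_equal(f$long_short_ratio$value, 4.0)

  # no silences -> zeros with a sentinel ratio
  f0 <- silence_features(s[0, ], stats)
  expect_equal(f0$duration_norm$value, 0)
  expect_equal(f0$count_norm$value, 0)
  expect_true(f0$long_short_ratio$missing)

  # the 300 ms boundary is exclusive for "long"
  s300 <- data.frame(start_ms = c(0, 500), end_ms = c(300, 800))
  expect_equal(silence_features(s300, stats)$long_short_ratio$value, 0)

  expect_error(silence_features(s, list(speaking_time_ms = 0)), "positive")
})

test_that("the canonical fixture reproduces the hand-computed vector exactly", {
  fx <- canonical_fixture()
  fv <- build_feature_vector(fx$t, fx$detections, fx$silences, fx$stats)
  expect_equal(fv$values, hand_expected, tolerance = 1e-12)
  expect_identical(unname(fv$missing), rep(FALSE, 18))
  # stable across repeated computation
  fv2 <- build_feature_vector(fx$t, fx$detections, fx$silences, fx$stats)
  expect_identical(fv$values, fv2$values)
})

test_that("hand detection lists and real detectors give identical vectors", {
  fx <- canonical_fixture()
  pats <- patient_utterances(fx$t)
  auto <- bind_detections(
    do.call(bind_detections, lapply(pats, keyword_search,
                                    ks = default_filler_keywords(),
                                    detection_type = "filler")),
    do.call(bind_detections, lapply(pats, detect_repetitions)),
    fx$detections[fx$detections$type == "substitution", ],
    do.call(bind_detections, lapply(pats, keyword_search,
                                    ks = default_vague_keywords(),
                                    detection_type = "vague")))
  fv_auto <- build_feature_vector(fx$t, auto, fx$silences, fx$stats)
  fv_hand <- build_feature_vector(fx$t, fx$detections, fx$silences, fx$stats)
  expect_equal(fv_auto$values, fv_hand$values, tolerance = 1e-12)
})

test_that("doubling the transcript leaves every rate and ratio unchanged", {
  fx <- canonical_fixture()
  texts <- vapply(fx$t$utterances, function(u) u$clean_text, character(1))
  t2 <- make_transcript(c(texts, texts))
  d2 <- fx$detections
  d2$utterance_index <- d2$utterance_index + length(texts)
  det2 <- rbind(fx$detections, d2)
  sil2 <- rbind(fx$silences,
                data.frame(start_ms = fx$silences$start_ms + 5000,
                           end_ms = fx$silences$end_ms + 5000))
  stats2 <- patient_speech_stats(t2, speaking_time_ms = 20000)
  fv1 <- build_feature_vector(fx$t, fx$detections, fx$silences, fx$stats)
  fv2 <- build_feature_vector(t2, det2, sil2, stats2)
  expect_equal(fv2$values, fv1$values, tolerance = 1e-12)
})

test_that("empty patient speech is rejected, empty detections are fine", {
  t <- make_transcript(".")
  expect_error(build_feature_vector(t, empty_detections_test(),
                                    data.frame(start_ms = 1, end_ms = 2),
                                    patient_speech_stats(t, 1000)),
               "no words")
  fx <- canonical_fixture()
  fv <- build_feature_vector(fx$t, empty_detections_test(), fx$silences,
                             fx$stats)
  expect_equal(unname(fv$values["filler_rate"]), 0)
  expect_true(fv$missing[["ifd_mean"]])
})

test_that("feature matrix and CSV writer keep the canonical column order", {
  fx <- canonical_fixture()
  fv <- build_feature_vector(fx$t, fx$detections, fx$silences, fx$stats)
  m <- feature_matrix(list(fv, fv))
  expect_equal(colnames(m), feature_names())
  expect_equal(nrow(m), 2L)
  path <- tempfile(fileext = ".csv")
  write_features_csv(list(fv), path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(names(back), c("subject_id", feature_names()))
  expect_equal(unlist(back[1, -1], use.names = FALSE), unname(fv$values))
})
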