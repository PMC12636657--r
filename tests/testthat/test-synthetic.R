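test_that("zero rates give a clean transcript; saturation marks everything", {
  cfg0 <- generator_config(filler_rate = 0, repetition_rate = 0,
                           substitution_rate = 0, vague_rate = 0,
                           pause_rate = 0)
  gen <- generate_transcript(cfg0, seed = 1)
  t <- parse_chat(gen$lines)
  for (u in patient_utterances(t)) expect_false(any(u$labels))

  cfg1 <- generator_config(filler_rate = 1)
  gen1 <- generate_transcript(cfg1, seed = 2)
  t1 <- parse_chat(gen1$lines)
  for (u in patient_utterances(t1)) expect_true(u$labels[["filler"]])
})

test_that("derived labels reproduce the planted ground truth exactly", {
  for (seed in 1:10) {
    cfg <- generator_config(filler_rate = 0.1, repetition_rate = 0.05,
                            substitution_rate = 0.04, vague_rate = 0.03,
                            pause_rate = 0.05)
    gen <- generate_transcript(cfg, seed = seed)
    t <- parse_chat(gen$lines)
    pats <- patient_utterances(t)
    expect_length(pats, length(gen$truth))
    for (k in seq_along(pats)) {
      expect_identical(pats[[k]]$labels, gen$truth[[k]]$labels,
                       label = sprintf("seed %d utterance %d", seed, k))
    }
  }
})

test_that("generated documents parse with no unknown-code warnings", {
  for (seed in 1:5) {
    gen <- generate_transcript(generator_config(filler_rate = 0.1,
                                                repetition_rate = 0.1,
                                                substitution_rate = 0.1,
                                                vague_rate = 0.1,
                                                pause_rate = 0.1),
                               seed = seed)
    expect_no_warning(parse_chat(gen$lines))
  }
})

test_that("generation is byte-identical given the seed", {
  cfg <- generator_config()
  g1 <- generate_transcript(cfg, seed = 42)
  g2 <- generate_transcript(cfg, seed = 42)
  expect_identical(g1$lines, g2$lines)
  a1 <- generate_audio(g1, cfg, seed = 7)
  a2 <- generate_audio(g2, cfg, seed = 7)
  expect_identical(a1$waveform$samples, a2$waveform$samples)
  # different seeds differ
  expect_false(identical(generate_transcript(cfg, seed = 43)$lines, g1$lines))
})

test_that("planted event frequencies match their nominal rates", {
  # ~10,000 word slots; each planted rate within 3 binomial standard errors
  cfg <- generator_config(filler_rate = 0.1, repetition_rate = 0.05,
                          substitution_rate = 0.03, vague_rate = 0.02,
                          pause_rate = 0.04, mean_utterances = 1100,
                          mean_words = 9, investigator_rate = 0)
  gen <- generate_transcript(cfg, seed = 5)
  slots <- sum(vapply(gen$truth, function(u)
    u$spoken_words - u$n_fillers - u$n_repetitions, numeric(1)))
  counts <- c(
    filler = sum(vapply(gen$truth, function(u) u$n_fillers, numeric(1))),
    repetition = sum(vapply(gen$truth, function(u) u$n_repetitions, numeric(1))),
    substitution = sum(vapply(gen$truth, function(u) u$n_substitutions,
                              numeric(1))),
    vague = sum(vapply(gen$truth, function(u) u$n_vague, numeric(1))),
    pause = sum(vapply(gen$truth, function(u) length(u$pauses), numeric(1))))
  nominal <- c(0.1, 0.05, 0.03, 0.02, 0.04)
  for (i in seq_along(nominal)) {
    se <- sqrt(nominal[i] * (1 - nominal[i]) / slots)
    expect_lt(abs(counts[i] / slots - nominal[i]), 3 * se,
              label = names(counts)[i])
  }
})

test_that("synthesized audio recovers planted pauses", {
  # no pauses -> nothing at -55 dBFS
  cfg <- generator_config(pause_rate = 0)
  gen <- generate_transcript(cfg, seed = 3)
  au <- generate_audio(gen, cfg, seed = 4)
  expect_equal(nrow(detect_silences(au$waveform)), 0L)

  # planted pauses -> one detected segment each, within one frame
  cfg2 <- generator_config(pause_rate = 0.08)
  gen2 <- generate_transcript(cfg2, seed = 9)
  au2 <- generate_audio(gen2, cfg2, seed = 10)
  det <- detect_silences(au2$waveform)
  expect_equal(nrow(det), nrow(au2$silences))
  expect_true(all(abs(det$start_ms - au2$silences$start_ms) <= 1))
  expect_true(all(abs(det$end_ms - au2$silences$end_ms) <= 1))
  # aggregate silent duration within 2% of planted
  planted <- sum(au2$silences$end_ms - au2$silences$start_ms)
  found <- sum(det$end_ms - det$start_ms)
  expect_lt(abs(found - planted) / planted, 0.02)
})

test_that("cohorts are labeled, balanced and deterministic", {
  spec <- cohort_spec(n_ci = 3, n_cn = 3, effect = c(filler = 3), seed = 21)
  coh <- generate_cohort(spec, audio = FALSE)
  labs <- vapply(coh$subjects, function(s) s$label, integer(1))
  expect_equal(sum(labs), 3L)
  expect_equal(sum(1 - labs), 3L)
  coh2 <- generate_cohort(spec, audio = FALSE)
  expect_identical(lapply(coh$subjects, function(s) s$lines),
                   lapply(coh2$subjects, function(s) s$lines))
})

test_that("cohorts write to disk as plain-text fixtures with provenance", {
  dir <- file.path(tempdir(), "cohort_fixture")
  on.exit(unlink(dir, recursive = TRUE))
  coh <- generate_cohort(cohort_spec(n_ci = 2, n_cn = 2, seed = 5))
  write_cohort(coh, dir)
  ids <- vapply(coh$subjects, function(s) s$id, character(1))
  for (id in ids) {
    expect_true(file.exists(file.path(dir, id, "transcript.cha")))
    expect_true(file.exists(file.path(dir, id, "audio.wav")))
    expect_true(file.exists(file.path(dir, id, "truth.json")))
  }
  labels <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(labels), 4L)
  prov <- jsonlite::fromJSON(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 5)
  expect_true(prov$null_cohort)
  # the written transcript parses back to the same labels
  t <- parse_chat(file.path(dir, ids[1], "transcript.cha"))
  pats <- patient_utterances(t)
  expect_identical(lapply(pats, function(u) unname(u$labels)),
                   lapply(coh$subjects[[1]]$truth, function(u) unname(u$labels)))
})
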