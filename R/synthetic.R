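# Synthetic fixtures: CHAT transcripts with planted indicator events at
# configurable per-word rates, matching audio with planted silences, and
# labeled case-control cohorts with controllable effect sizes. The generator's
# defaults emulate the prevalence structure of picture-description corpora
# (roughly 18% / 6% / 2.5% / 1% / 7% of utterances positive for filler /
# repetition / substitution / vague / delay at ~13 utterances of ~9 words per
# subject). Statistical structure, not linguistic realism, is the goal.

#' Synthetic transcript generator configuration
#'
#' Per-indicator event rates are probabilities per patient word slot.
#'
#' @param filler_rate probability of planting a `&`-prefixed filler before a
#'   word (default 0.025).
#' @param repetition_rate probability of replacing a word by `word [/] word`
#'   (default 0.008).
#' @param substitution_rate probability of replacing a word by an
#'   out-of-vocabulary error word tagged `[*]` (default 0.003).
#' @param vague_rate probability of replacing a word by a vague term and
#'   tagging the utterance `[+ es]`/`[+ cir]` (default 0.001).
#' @param pause_rate probability of planting a pause code before a word
#'   (default 0.008).
#' @param pause_mu_log,pause_sigma log-normal pause duration parameters in ms
#'   (defaults `log(600)` and 0.5).
#' @param mean_utterances,mean_words Poisson means for the number of patient
#'   utterances (default 13) and words per utterance (default 9).
#' @param investigator_rate probability of an investigator backchannel between
#'   patient utterances (default 0.2).
#' @param sample_rate audio sampling rate in Hz (default 16000).
#' @param word_ms speech duration per spoken word (default 200 ms).
#' @param speech_dbfs level of the speech-noise bursts (default -20 dBFS,
#'   safely above the -55 dBFS silence threshold).
#' @param vocab sampling vocabulary (named by coarse part of speech); defaults
#'   to the built-in picture-description vocabulary.
#' @export
generator_config <- function(filler_rate = 0.025, repetition_rate = 0.008,
                             substitution_rate = 0.003, vague_rate = 0.001,
                             pause_rate = 0.008,
                             pause_mu_log = log(600), pause_sigma = 0.5,
                             mean_utterances = 13, mean_words = 9,
                             investigator_rate = 0.2,
                             sample_rate = 16000, word_ms = 200,
                             speech_dbfs = -20,
                             vocab = default_generator_vocab()) {
  rates <- c(filler_rate, repetition_rate, substitution_rate, vague_rate,
             pause_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), pause_sigma >= 0,
            mean_utterances > 0, mean_words > 0, sample_rate > 0,
            word_ms >= 1, speech_dbfs < 0)
  structure(list(filler_rate = filler_rate, repetition_rate = repetition_rate,
                 substitution_rate = substitution_rate,
                 vague_rate = vague_rate, pause_rate = pause_rate,
                 pause_mu_log = pause_mu_log, pause_sigma = pause_sigma,
                 mean_utterances = mean_utterances, mean_words = mean_words,
                 investigator_rate = investigator_rate,
                 sample_rate = sample_rate, word_ms = word_ms,
                 speech_dbfs = speech_dbfs, vocab = vocab),
            class = "generator_config")
}

#' Built-in picture-description sampling vocabulary
#' @return character vector of words, named by coarse part of speech.
#' @export
default_generator_vocab <- function() {
  w <- function(words, t) stats::setNames(words, rep(t, length(words)))
  c(
    w(c("boy", "girl", "cookie", "jar", "sink", "water", "mother", "stool",
        "window", "plate", "curtain", "kitchen", "counter", "cupboard"),
      "noun"),
    w(c("falls", "reaches", "takes", "washes", "overflows", "stands",
        "dries", "climbs", "spills", "is"), "verb"),
    w(c("little", "tall", "wet", "full", "open"), "adjective"),
    w(c("quickly", "there", "down", "over"), "adverb"),
    w(c("he", "she", "it", "they"), "pronoun"),
    w(c("the", "a", "an"), "determiner")
  )
}

.FILLER_WORDS <- c("um", "uh", "er", "ah")
.ERROR_WORDS <- c("flib", "trolk", "dabber", "snorp", "glimmet", "parkle")
.VAGUE_WORDS <- c("thing", "stuff", "something")
.PAUSE_CODES <- c("(.)", "(..)", "(…)")

sample_pause_ms <- function(cfg) {
  max(20, round(stats::rlnorm(1, cfg$pause_mu_log, cfg$pause_sigma)))
}

# sample one content word with crude part-of-speech mixture weights
sample_word <- function(vocab) {
  pos <- sample(c("determiner", "noun", "verb", "pronoun", "adjective",
                  "adverb"), 1,
                prob = c(0.18, 0.30, 0.22, 0.12, 0.08, 0.10))
  cand <- vocab[names(vocab) == pos]
  if (!length(cand)) cand <- vocab
  unname(sample(cand, 1))
}

#' Generate one synthetic CHAT transcript with planted events
#'
#' Emits a syntactically valid CHAT document whose patient tier carries
#' planted indicator events encoded with the standard codes (`&`-prefixed
#' fillers, `word [/] word` repetitions, `[*]`-tagged error words, `[+ es]` /
#' `[+ cir]` postcodes, pause codes) plus a ground-truth event record. Parsing
#' the document and deriving labels recovers the planted per-utterance label
#' pattern exactly.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed; generation is fully determined by it.
#' @param subject_id subject identifier written into the `@PID` header.
#' @return list with `lines` (the CHAT document), `truth` (per-utterance
#'   ground truth: labels, event counts, pause durations, spoken word counts),
#'   `audio_plan` (ordered speech/pause segments in ms) and
#'   `patient_speech_ms`.
#' @export
generate_transcript <- function(cfg = generator_config(), seed = 1L,
                                subject_id = "synthetic") {
  stopifnot(inherits(cfg, "generator_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  n_utt <- max(4L, stats::rpois(1, cfg$mean_utterances))
  lines <- c("@Begin", "@Languages:\teng",
             "@Participants:\tPAR Participant, INV Investigator",
             paste0("@PID:\t", subject_id))
  truth <- list()
  plan <- list()  # list of c(type = "speech"/"pause", ms)
  patient_speech_ms <- 0

  add_speech <- function(n_words) {
    ms <- n_words * cfg$word_ms
    if (length(plan) && plan[[length(plan)]]$type == "speech") {
      plan[[length(plan)]]$ms <<- plan[[length(plan)]]$ms + ms
    } else {
      plan[[length(plan) + 1L]] <<- list(type = "speech", ms = ms)
    }
  }
  add_pause <- function(ms) {
    plan[[length(plan) + 1L]] <<- list(type = "pause", ms = ms)
  }

  for (k in seq_len(n_utt)) {
    L <- max(3L, stats::rpois(1, cfg$mean_words))
    toks <- character()
    n_fil <- n_rep <- n_sub <- n_vag <- 0L
    pauses <- numeric()
    spoken <- 0L  # lexical words actually spoken (incl. fillers and repeats)
    vague_code <- NULL

    for (i in seq_len(L)) {
      if (stats::runif(1) < cfg$pause_rate) {
        dur <- sample_pause_ms(cfg)
        pauses <- c(pauses, dur)
        toks <- c(toks, sample(.PAUSE_CODES, 1))
        add_pause(dur)
      }
      if (stats::runif(1) < cfg$filler_rate) {
        toks <- c(toks, paste0("&", sample(.FILLER_WORDS, 1)))
        n_fil <- n_fil + 1L
        spoken <- spoken + 1L
        add_speech(1L)
      }
      w <- sample_word(cfg$vocab)
      u <- stats::runif(1)
      if (u < cfg$repetition_rate) {
        toks <- c(toks, w, "[/]", w)
        n_rep <- n_rep + 1L
        spoken <- spoken + 2L
        add_speech(2L)
      } else if (u < cfg$repetition_rate + cfg$substitution_rate) {
        toks <- c(toks, sample(.ERROR_WORDS, 1),
                  sample(c("[* s]", "[* n]"), 1))
        n_sub <- n_sub + 1L
        spoken <- spoken + 1L
        add_speech(1L)
      } else if (u < cfg$repetition_rate + cfg$substitution_rate +
                 cfg$vague_rate) {
        toks <- c(toks, sample(.VAGUE_WORDS, 1))
        n_vag <- n_vag + 1L
        vague_code <- sample(c("[+ es]", "[+ cir]"), 1)
        spoken <- spoken + 1L
        add_speech(1L)
      } else {
        toks <- c(toks, w)
        spoken <- spoken + 1L
        add_speech(1L)
      }
    }
    if (!is.null(vague_code)) toks <- c(toks, vague_code)
    body <- paste(c(toks, "."), collapse = " ")
    lines <- c(lines, paste0("*PAR:\t", body))
    patient_speech_ms <- patient_speech_ms + spoken * cfg$word_ms
    truth[[length(truth) + 1L]] <- list(
      speaker = "PAR",
      labels = c(filler = n_fil > 0, repetition = n_rep > 0,
                 substitution = n_sub > 0, vague = n_vag > 0,
                 delay = length(pauses) > 0),
      n_fillers = n_fil, n_repetitions = n_rep, n_substitutions = n_sub,
      n_vague = n_vag, pauses = pauses, spoken_words = spoken)

    if (stats::runif(1) < cfg$investigator_rate) {
      lines <- c(lines, "*INV:\tokay .")
      add_speech(1L)
    }
  }
  lines <- c(lines, "@End")
  list(lines = lines, truth = truth, audio_plan = plan,
       patient_speech_ms = patient_speech_ms, subject_id = subject_id)
}

#' Synthesize audio matching a generated transcript
#'
#' Speech spans become Gaussian noise bursts at `cfg$speech_dbfs` (default
#' -20 dBFS, far above the silence threshold); planted pauses become
#' zero-amplitude gaps of exactly the planted duration. All boundaries are
#' quantized to whole milliseconds.
#'
#' @param gen output of [generate_transcript()].
#' @param cfg the [generator_config()] used to generate it.
#' @param seed integer seed for the noise.
#' @return list with `waveform` (a [waveform()]) and `silences` (ground-truth
#'   segment data.frame).
#' @export
generate_audio <- function(gen, cfg = generator_config(), seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  amp <- 10^(cfg$speech_dbfs / 20)
  sr <- cfg$sample_rate
  pieces <- vector("list", length(gen$audio_plan))
  t_ms <- 0
  sil <- list()
  for (i in seq_along(gen$audio_plan)) {
    seg <- gen$audio_plan[[i]]
    n <- round(seg$ms * sr / 1000)
    if (seg$type == "speech") {
      pieces[[i]] <- pmax(-1, pmin(1, stats::rnorm(n, sd = amp)))
    } else {
      pieces[[i]] <- numeric(n)
      sil[[length(sil) + 1L]] <- c(t_ms, t_ms + seg$ms)
    }
    t_ms <- t_ms + seg$ms
  }
  silences <- if (length(sil)) {
    m <- do.call(rbind, sil)
    data.frame(start_ms = m[, 1], end_ms = m[, 2])
  } else {
    empty_segments()
  }
  list(waveform = waveform(unlist(pieces), sr), silences = silences)
}

#' Cohort specification for synthetic case-control data
#'
#' @param n_ci,n_cn subject counts per group (defaults 30/30).
#' @param effect multiplicative rate shift applied to the impaired group:
#'   a scalar for all indicators or a named vector over
#'   `filler`, `repetition`, `substitution`, `vague`, `pause` (default 1 =
#'   null cohort).
#' @param base_config base [generator_config()] shared by both groups.
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_ci = 30, n_cn = 30, effect = 1,
                        base_config = generator_config(), seed = 1L) {
  stopifnot(n_ci >= 0, n_cn >= 0, all(effect >= 0))
  if (length(effect) > 1 || !is.null(names(effect))) {
    stopifnot(all(names(effect) %in% c("filler", "repetition", "substitution",
                                       "vague", "pause")))
  }
  structure(list(n_ci = n_ci, n_cn = n_cn, effect = effect,
                 base_config = base_config, seed = seed),
            class = "cohort_spec")
}

apply_effect <- function(cfg, effect) {
  mult <- stats::setNames(rep(1, 5), c("filler", "repetition", "substitution",
                                       "vague", "pause"))
  if (is.null(names(effect))) mult[] <- effect
  else mult[names(effect)] <- effect
  cfg$filler_rate <- min(1, cfg$filler_rate * mult[["filler"]])
  cfg$repetition_rate <- min(1, cfg$repetition_rate * mult[["repetition"]])
  cfg$substitution_rate <- min(1, cfg$substitution_rate * mult[["substitution"]])
  cfg$vague_rate <- min(1, cfg$vague_rate * mult[["vague"]])
  cfg$pause_rate <- min(1, cfg$pause_rate * mult[["pause"]])
  cfg
}

#' Generate a labeled synthetic cohort
#'
#' Cognitively normal subjects are drawn at the base rates; impaired subjects
#' at base rates times the per-indicator effect. Deterministic given the seed.
#'
#' @param spec a [cohort_spec()].
#' @param audio generate matching audio (default TRUE).
#' @return object of class `synthetic_cohort`: list with `subjects` (each a
#'   list with `id`, `label`, `age`, `sex`, `lines`, `transcript`, `truth`,
#'   `audio_plan`, `waveform`, `silences`) and the generating `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), audio = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_ci + spec$n_cn
  subject_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  labels <- c(rep(1L, spec$n_ci), rep(0L, spec$n_cn))
  ages <- round(stats::rnorm(n, 66, 7))
  sexes <- sample(c("female", "male"), n, replace = TRUE)

  ci_cfg <- apply_effect(spec$base_config, spec$effect)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- if (labels[i] == 1L) ci_cfg else spec$base_config
    id <- sprintf("S%03d_%s", i, if (labels[i] == 1L) "ci" else "cn")
    gen <- generate_transcript(cfg, seed = subject_seeds[2 * i - 1L],
                               subject_id = id)
    subj <- list(id = id, label = labels[i], age = ages[i], sex = sexes[i],
                 lines = gen$lines,
                 transcript = parse_chat(gen$lines, subject_id = id),
                 truth = gen$truth, audio_plan = gen$audio_plan,
                 patient_speech_ms = gen$patient_speech_ms)
    if (audio) {
      au <- generate_audio(gen, cfg, seed = subject_seeds[2 * i])
      subj$waveform <- au$waveform
      subj$silences <- au$silences
    }
    subjects[[i]] <- subj
  }
  structure(list(subjects = subjects, spec = spec,
                 vocab = unname(spec$base_config$vocab)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, function(s) s$label, integer(1))
  cat(sprintf("<synthetic_cohort> %d subjects (%d impaired / %d normal), effect %s\n",
              length(labs), sum(labs), sum(1 - labs),
              paste(format(x$spec$effect), collapse = "/")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One directory per subject with `transcript.cha`, `audio.wav` (16-bit PCM)
#' and `truth.json`; a cohort-level `labels.csv` and a provenance file
#' recording the spec and seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(id = character(), label = integer(), age = numeric(),
                     sex = character())
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    writeLines(s$lines, file.path(sd, "transcript.cha"), useBytes = TRUE)
    if (!is.null(s$waveform)) write_wav(s$waveform, file.path(sd, "audio.wav"))
    jsonlite::write_json(
      list(labels = lapply(s$truth, function(u) as.list(u$labels)),
           silences = if (!is.null(s$silences))
             mapply(c, s$silences$start_ms, s$silences$end_ms,
                    SIMPLIFY = FALSE) else list()),
      file.path(sd, "truth.json"), auto_unbox = TRUE, digits = NA)
    meta <- rbind(meta, data.frame(id = s$id, label = s$label, age = s$age,
                                   sex = s$sex))
  }
  utils::write.csv(meta, file.path(dir, "labels.csv"), row.names = FALSE)
  spec <- cohort$spec
  jsonlite::write_json(
    list(n_ci = spec$n_ci, n_cn = spec$n_cn, effect = as.list(spec$effect),
         seed = spec$seed,
         null_cohort = all(spec$effect == 1),
         package_version = as.character(utils::packageVersion("cogspeech"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
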