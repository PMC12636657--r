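# Stage orchestration: run the three stages end to end for one subject, and
# train the stage-3 classifier on a cohort. Detector backends are selectable
# per indicator; a failing detector degrades to an empty detection list with a
# prominent warning, never a crash.

#' Run all stage-1 detectors on a transcript
#'
#' @param t a `chat_transcript`.
#' @param detectors named character vector choosing a backend per indicator:
#'   `filler` and `vague` in `{"keyword", "llm", "none"}`; `repetition` in
#'   `{"unigram", "llm", "none"}`; `substitution` in `{"mlm", "llm", "none"}`.
#'   Defaults are the traditional baselines.
#' @param filler_keywords,vague_keywords [keyword_set()]s (package defaults).
#' @param repetition_cfg a [repetition_config()].
#' @param substitution_cfg a [substitution_config()].
#' @param sub_backend masked-prediction backend for the MLM route; default is
#'   a corpus unigram-frequency backend built from the patient's own tokens.
#' @param llm_client client function for the LLM routes (required if any
#'   indicator selects `"llm"`).
#' @return detection data.frame over all indicators.
#' @export
detect_all <- function(t,
                       detectors = c(filler = "keyword",
                                     repetition = "unigram",
                                     substitution = "mlm",
                                     vague = "keyword"),
                       filler_keywords = default_filler_keywords(),
                       vague_keywords = default_vague_keywords(),
                       repetition_cfg = repetition_config(),
                       substitution_cfg = substitution_config(),
                       sub_backend = NULL,
                       llm_client = NULL) {
  stopifnot(inherits(t, "chat_transcript"))
  pats <- patient_utterances(t)
  guarded <- function(indicator, fn) {
    tryCatch(fn(), error = function(e) {
      warning(sprintf("%s detector failed (%s); continuing with no detections",
                      indicator, conditionMessage(e)), call. = FALSE)
      empty_detections()
    })
  }
  run_llm <- function(indicator) {
    if (is.null(llm_client)) stop("llm backend selected but no client supplied")
    llm_detect(t, default_prompt_spec(indicator), llm_client)
  }

  fil <- switch(detectors[["filler"]],
    keyword = guarded("filler", function()
      do.call(bind_detections, lapply(pats, keyword_search,
                                      ks = filler_keywords,
                                      detection_type = "filler"))),
    llm = guarded("filler", function() run_llm("filler")),
    none = empty_detections())
  rep_ <- switch(detectors[["repetition"]],
    unigram = guarded("repetition", function()
      do.call(bind_detections, lapply(pats, detect_repetitions,
                                      cfg = repetition_cfg))),
    llm = guarded("repetition", function() run_llm("repetition")),
    none = empty_detections())
  sub <- switch(detectors[["substitution"]],
    mlm = guarded("substitution", function() {
      backend <- sub_backend
      if (is.null(backend)) {
        toks <- unlist(lapply(pats, function(u)
          u$tokens$token[is_lexical_token(u$tokens$token)]))
        backend <- mlm_backend_frequency(toks)
      }
      suppressWarnings(detect_substitutions(t, backend, substitution_cfg))
    }),
    llm = guarded("substitution", function() run_llm("substitution")),
    none = empty_detections())
  vag <- switch(detectors[["vague"]],
    keyword = guarded("vague", function()
      do.call(bind_detections, lapply(pats, keyword_search,
                                      ks = vague_keywords,
                                      detection_type = "vague"))),
    llm = guarded("vague", function() run_llm("vague")),
    none = empty_detections())

  bind_detections(fil, rep_, sub, vag)
}

#' Run the full three-stage pipeline for one subject
#'
#' Stage 1 detects indicator events on the transcript and silences on the
#' audio; stage 2 aggregates them into the summary feature vector; stage 3
#' (when a fitted model is supplied) produces the explainable diagnostic
#' profile.
#'
#' @param transcript a `chat_transcript` or path to a `.cha` file.
#' @param audio a [waveform()] or path to a WAV file.
#' @param model optional fitted `ci_model`.
#' @param silence_cfg a [silence_config()].
#' @param speaking_time_ms the patient's speaking time; when `NA` (default)
#'   the fallback total audio duration minus detected silence is used and
#'   flagged in the result.
#' @param tagger part-of-speech provider.
#' @param out_dir optional output directory: writes `detections.json`,
#'   `silences.json`, `features.csv`, and (with a model) `profile.json` plus a
#'   `provenance.json`.
#' @inheritParams detect_all
#' @return list with `features` (a `feature_vector`), `detections`,
#'   `silences`, `speaking_time_fallback` flag and, when a model is given,
#'   `profile`.
#' @export
run_pipeline <- function(transcript, audio, model = NULL,
                         detectors = c(filler = "keyword",
                                       repetition = "unigram",
                                       substitution = "mlm",
                                       vague = "keyword"),
                         silence_cfg = silence_config(),
                         speaking_time_ms = NA_real_,
                         tagger = lexicon_tagger(),
                         sub_backend = NULL, llm_client = NULL,
                         filler_keywords = default_filler_keywords(),
                         vague_keywords = default_vague_keywords(),
                         repetition_cfg = repetition_config(),
                         substitution_cfg = substitution_config(),
                         out_dir = NULL) {
  if (is.character(transcript)) {
    if (!file.exists(transcript)) {
      stop("transcript not readable: ", transcript, call. = FALSE)
    }
    transcript <- parse_chat(transcript)
  }
  if (is.character(audio)) {
    if (!file.exists(audio)) stop("audio not readable: ", audio, call. = FALSE)
    audio <- read_wav(audio)
  }
  stopifnot(inherits(transcript, "chat_transcript"), inherits(audio, "waveform"))

  detections <- detect_all(transcript, detectors = detectors,
                           filler_keywords = filler_keywords,
                           vague_keywords = vague_keywords,
                           repetition_cfg = repetition_cfg,
                           substitution_cfg = substitution_cfg,
                           sub_backend = sub_backend, llm_client = llm_client)
  silences <- detect_silences(audio, silence_cfg)

  fallback <- is.na(speaking_time_ms)
  if (fallback) {
    speaking_time_ms <- duration_ms(audio) -
      sum(silences$end_ms - silences$start_ms)
  }
  stats <- patient_speech_stats(transcript, speaking_time_ms)
  fv <- build_feature_vector(transcript, detections, silences, stats, tagger)

  out <- list(features = fv, detections = detections, silences = silences,
              speaking_time_fallback = fallback)
  if (!is.null(model)) {
    out$profile <- build_profile(fv$values, model,
                                 detections = split(detections,
                                                    detections$type),
                                 subject_id = transcript$subject_id)
    out$profile$provenance$speaking_time_fallback <- fallback
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    detections_to_json(detections, file.path(out_dir, "detections.json"))
    silences_to_json(silences, file.path(out_dir, "silences.json"))
    write_features_csv(list(fv), file.path(out_dir, "features.csv"))
    if (!is.null(out$profile)) {
      write_profile_json(out$profile, file.path(out_dir, "profile.json"))
    }
    jsonlite::write_json(
      list(detectors = as.list(detectors),
           silence_config = unclass(silence_cfg),
           speaking_time_fallback = fallback,
           package_version = as.character(utils::packageVersion("cogspeech"))),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  }
  out
}

#' Extract the feature matrix of a synthetic cohort
#'
#' Runs stages 1 and 2 for every subject of a [generate_cohort()] result using
#' the baseline detectors: keyword filler/vague search, unigram repetition
#' detection, the masked-language-model substitution scorer with the
#' vocabulary stub backend (planted error words are out-of-vocabulary), and
#' the amplitude-threshold silence detector on the synthesized audio.
#'
#' @param cohort a `synthetic_cohort` (generated with audio).
#' @param silence_cfg a [silence_config()].
#' @param tagger part-of-speech provider.
#' @return list with `features` (matrix, subjects x features), `labels`
#'   (named integer vector) and `meta` (data.frame id/label/age/sex).
#' @export
cohort_features <- function(cohort, silence_cfg = silence_config(),
                            tagger = lexicon_tagger()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  backend <- mlm_backend_stub(c(cohort$vocab, .FILLER_WORDS, .VAGUE_WORDS))
  fvs <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    if (is.null(s$waveform)) stop("cohort generated without audio", call. = FALSE)
    res <- run_pipeline(s$transcript, s$waveform,
                        silence_cfg = silence_cfg, tagger = tagger,
                        sub_backend = backend)
    fvs[[i]] <- res$features
  }
  feats <- feature_matrix(fvs)
  labels <- stats::setNames(vapply(cohort$subjects, function(s) s$label,
                                   integer(1)),
                            vapply(cohort$subjects, function(s) s$id,
                                   character(1)))
  meta <- data.frame(
    id = names(labels), label = unname(labels),
    age = vapply(cohort$subjects, function(s) s$age, numeric(1)),
    sex = vapply(cohort$subjects, function(s) s$sex, character(1)))
  list(features = feats, labels = labels, meta = meta)
}

#' Train the stage-3 classifier on a cohort and evaluate it
#'
#' @param cohort a `synthetic_cohort`, or a list with `features` and `labels`
#'   (as from [cohort_features()]).
#' @param config a [model_config()].
#' @param plan a [cv_plan()].
#' @param seed integer seed.
#' @param n_bootstrap bootstrap replicates for the metric confidence
#'   intervals (default 1000).
#' @return list with `model` (a `ci_model`) and `metrics` (from [evaluate()],
#'   computed on the cross-validated per-subject mean probabilities).
#' @export
train_pipeline <- function(cohort, config = model_config(), plan = cv_plan(),
                           seed = 1L, n_bootstrap = 1000) {
  data <- if (inherits(cohort, "synthetic_cohort")) cohort_features(cohort)
          else cohort
  stopifnot(!is.null(data$features), !is.null(data$labels))
  model <- ci_train(data$features, data$labels, config = config, plan = plan,
                    seed = seed)
  metrics <- evaluate(model$prob, model$labels, n_bootstrap = n_bootstrap,
                      seed = seed)
  list(model = model, metrics = metrics)
}
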