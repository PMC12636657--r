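---
title: "Methods: a three-stage pipeline for cognitive-impairment indicators in speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-stage pipeline for cognitive-impairment indicators in speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogspeech)
```

## Overview

`cogspeech` screens for cognitive impairment (CI) from a single speech
sample: a diarized transcript in the CHAT dialect plus the matching audio
recording. The design is a strictly modular three-stage pipeline:

1. **Indicator detection.** Independent detectors scan the patient's speech
   for five clinically motivated indicators — *filler speech* (um, uh),
   *repetitive speech*, *substitution errors* (paraphasias), *vague speech*
   (circumlocution, empty terms), and *speech delays* (long silences).
   Every detector emits the same `Detection` record (type, matched text,
   character span(s), utterance index, optional justification), so backends
   are swappable without touching anything downstream.
2. **Summary features.** Detections and silence segments are aggregated
   into an 18-component vector of interpretable rates, inter-event
   distances, and silence statistics.
3. **Prediction.** A cross-validated gradient-boosted stump classifier maps
   the feature vector to a CI probability and an additive per-feature
   attribution — the *diagnostic profile* a clinician can read.

Because real clinical corpora are access-restricted, the package also ships
a synthetic-cohort generator that plants known indicator events into
CHAT transcripts and synthesized audio, giving ground truth against which
every stage is validated.

## Stage 1: detectors

### Transcript preprocessing and label derivation

`parse_chat()` reads CHAT files: `@` headers, `*SPK:` speaker tiers with
continuation lines, `%` dependent tiers. `preprocess_utterance()` rewrites
inline codes into a normalized clean form: filler prefixes `&w`/`&-w`
become plain words, `&=event` codes become the `[<event>]` sentinel, pause
codes `(.)`, `(..)`, `(...)` (the `(…)` glyph is also accepted) become
`[silence]`, unintelligible stretches become `[inaudible]`. Rewriting is
idempotent, and unknown bracket codes raise a classed warning rather than
being silently dropped.

Reference labels per utterance come from the coding itself
(`derive_labels()`): filler ⇔ an `&`-prefixed word (note `&=` marks an
*event*, not a filler — treating events as fillers would label every laugh
as disfluent), repetition ⇔ the retracing code `[/]`, substitution ⇔ any
word-error code `[*]`, vague ⇔ the postcodes `[+ es]` or `[+ cir]`, delay
⇔ any pause code.

### Silence detection

`detect_silences()` frames the waveform at 1 ms, computes per-frame RMS in
dBFS, and merges consecutive frames at or below **−55 dBFS** into segments,
keeping those at least **10 ms** long. Operative *speech delays* are
segments longer than **1,950 ms** (`speech_delay_segments()`). Detection is
monotone in both threshold and minimum duration.

### Lexical detectors

- **Fillers and vague terms**: case-insensitive token-aligned keyword
  search (`keyword_search()`) against editable keyword lists shipped in
  `inst/extdata/keywords/`. Multi-word terms are matched longest-first with
  greedy non-overlap resolution.
- **Repetitions**: a windowed unigram comparison (`detect_repetitions()`)
  flags a word that exactly matches (case-insensitively) a word at most
  **K = 2** positions earlier. Sentinels (`[silence]` etc.) are removed from
  the stream; punctuation occupies window slots but never matches. When
  several previous positions match, the nearest is reported.
- **Substitutions**: each patient word is masked in turn and scored by a
  pluggable probability backend. Two deterministic backends ship: a
  vocabulary stub and a leave-one-out unigram-frequency model (an adapter
  for a pretrained masked language model can be plugged in where one is
  available). Per word we compute the **normalized entropy**
  H(p)/log V and the **top-k concentration ratio** (k = 5), fused as
  0.5·NE + 0.5·(1 − CR). Words scoring strictly above the per-transcript
  **90th percentile** are flagged.
- **LLM adapters**: `llm_detect()` wraps any text-completion client behind
  the same `Detection` interface, with deterministic prompt assembly,
  robust JSON extraction, span validation with ±1 repair, and invalid
  responses dropped (logged), never fatal.

## Stage 2: summary features

`build_feature_vector()` computes, per subject:

- rates per spoken word: `filler_rate`, `repetition_rate` (plus six
  part-of-speech splits: noun, verb, adjective, adverb, pronoun,
  determiner), `substitution_rate`, `vague_terms_rate`;
- pooled inter-detection distances: `ifd_mean`/`ifd_std` (fillers) and
  `ised_mean`/`ised_std` (substitutions), counting lexical words strictly
  between consecutive detections within an utterance, pooled across
  utterances, with the population standard deviation;
- `vague_utterance_ratio`: fraction of utterances containing a vague
  detection;
- silence statistics normalized by patient speaking time:
  `silence_duration_norm`, `silence_count_norm`, and
  `long_short_silence_ratio` with the long/short cutoff at 300 ms
  (strictly greater than).

Undefined quantities (no detections → no gaps; no short silences) are set
to 0 and flagged in a missing-value mask rather than propagated as `NaN`.
The vector has **18 components**: the canonical feature table defines 17,
and the part-of-speech operation also yields a determiner rate, which the
feature layer keeps (the model's preprocessing drops any zero-variance
column anyway).

If no diarized speaking time is available, `run_pipeline()` falls back to
recording duration minus detected silence, and flags that it did.

## Stage 3: classifier

`ci_train()` fits a hand-written gradient-boosted **stump** (depth-1)
classifier with logistic loss. Defaults mirror a realistic clinical
configuration: up to 10,000 trees with early stopping at patience 50 on an
inner stratified 80/20 split of each training fold, minimum **12 samples
per leaf** (a count, which is why an off-the-shelf booster whose leaf
constraint is a hessian sum would not express it), L1 soft-thresholding of
leaf weights (α = 1.0), no L2, 20 % feature subsampling per tree, and
learning rate 0.1. Min–max scaling and zero-variance-column removal are fit
on the training fold only.

Evaluation uses subject-level cross-validation — leave-one-out or
10×10 repeated stratified k-fold (`cv_plan()`) — with **hard voting**
across folds (ties positive) and per-subject probabilities averaged over
validating folds. `evaluate()` reports AUC (via pROC), F1, precision,
recall, and accuracy with percentile-bootstrap confidence intervals.

Because every tree is a stump, each tree credits exactly one feature, so
`build_profile()` decomposes the raw margin into per-feature contributions
that sum to the margin **exactly** (to double precision), giving a faithful
additive explanation rather than an approximation.

## Numerical conventions

- **Percentile**: the substitution flag threshold uses the Weibull plotting
  position (R `quantile(type = 6)`). Under this convention the number of
  flagged words among n distinct scores equals n − ⌈n·p/100⌉, a clean
  order-statistics identity that the default type 7 does not satisfy.
- **Ties and boundaries**: silence threshold is inclusive (≤ −55 dBFS);
  substitution flags are strictly above the percentile; the long/short
  silence cutoff is strictly above 300 ms; voting ties go positive.
- **Sentinels**: undefined features are 0 plus a mask bit, never `NaN`.
- **Spans**: all character spans are 0-based, half-open, on the clean
  utterance text.
- **Seeds**: every stochastic step takes an explicit seed, saves and
  restores the global RNG state, and derived seeds stay below 2³¹.

## Synthetic generator: scope and limits

`generate_transcript()` plants events per word slot at configurable rates.
The defaults (filler 0.025, repetition 0.008, substitution 0.003, vague
0.001, pause 0.008 per word; ~13 utterances × ~9 words per subject)
reproduce utterance-level prevalences typical of picture-description
corpora (roughly 18 % filler, 6 % repetition, 2.5 % substitution, 1 %
vague, 7 % delayed utterances). Pause durations are log-normal
(median 600 ms, σ = 0.5 on the log scale, floor 20 ms). `generate_audio()`
synthesizes 16 kHz noise at −20 dBFS for speech (200 ms per word) and
digital zero for pauses. `generate_cohort()` builds labeled CI/CN cohorts
where the CI group's rates are multiplied by an effect size (1.0 = null
cohort, recorded in the provenance).

The generator validates the *machinery*, not the clinical claim: its
transcripts are exchangeable bags of events, with none of the syntactic,
topical, or acoustic structure of real patient speech. Performance numbers
on synthetic cohorts measure parameter recovery, not expected clinical
accuracy.

## Known limitations

- No pretrained masked language model or neural POS tagger is bundled;
  the shipped substitution backends and the lexicon tagger are
  deterministic stand-ins behind the same interfaces.
- The CHAT parser covers the coding subset used by the five indicators,
  not the full CLAN specification.
- The WAV reader handles PCM 16/24/32-bit integer and 32-bit float, mono
  or averaged-to-mono.
- Diarization is taken from the transcript; the audio stage assumes the
  recording is dominated by the patient when the speaking-time fallback is
  used.
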