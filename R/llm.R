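# Optional LLM-prompted detectors. The package never talks to a vendor API:
# a client is any function(prompt) -> response text, decoding parameters are
# fixed constants (temperature 0, top_p 1), and a scripted mock client makes
# the whole path testable offline. Shipped prompt texts are reconstructions of
# the template structure (persona, definition, rules, few-shot examples, JSON
# output contract); the wording is editable.

#' Fixed decoding contract for LLM clients
#'
#' Decoding parameters are constants, not tunables: temperature 0 and top_p 1
#' for reproducibility. Filler and repetition detectors run per utterance;
#' substitution and vague detectors see the whole transcript at once.
#' @export
llm_client_contract <- function() {
  list(temperature = 0, top_p = 1,
       granularity = c(filler = "utterance", repetition = "utterance",
                       substitution = "transcript", vague = "transcript"))
}

#' Construct a prompt specification
#'
#' @param indicator one of `"filler"`, `"repetition"`, `"substitution"`,
#'   `"vague"`.
#' @param persona persona framing text (a neurologist reviewing a transcript).
#' @param definition indicator definition text.
#' @param rules character vector of detection rules.
#' @param few_shot_examples list of `list(input =, output =)` pairs (output is
#'   the expected JSON text).
#' @param output_schema required JSON keys; must contain `type`, `text`,
#'   `span`; contains `span2` iff the indicator is repetition; may contain
#'   `justification` for substitution.
#' @export
prompt_spec <- function(indicator, persona, definition, rules,
                        few_shot_examples = list(),
                        output_schema = NULL) {
  stopifnot(indicator %in% c("filler", "repetition", "substitution", "vague"))
  if (is.null(output_schema)) {
    output_schema <- c("type", "text", "span")
    if (indicator == "repetition") output_schema <- c(output_schema, "span2")
    if (indicator == "substitution") output_schema <- c(output_schema, "justification")
  }
  stopifnot(all(c("type", "text", "span") %in% output_schema))
  if (indicator == "repetition") stopifnot("span2" %in% output_schema)
  else stopifnot(!"span2" %in% output_schema)
  structure(list(indicator = indicator, persona = persona,
                 definition = definition, rules = rules,
                 few_shot_examples = few_shot_examples,
                 output_schema = output_schema),
            class = "prompt_spec")
}

#' Default prompt specification for an indicator
#'
#' Loads the shipped (reconstructed, editable) definition and rules from
#' `inst/extdata/prompts/<indicator>.txt`. Defaults follow the study design:
#' filler and substitution prompts are zero-shot, repetition and vague prompts
#' carry few-shot examples; the substitution schema adds a `justification`
#' key (chain-of-thought).
#'
#' @param indicator indicator name.
#' @export
default_prompt_spec <- function(indicator) {
  path <- system.file("extdata", "prompts", paste0(indicator, ".txt"),
                      package = "cogspeech", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  def_end <- which(lines == "## rules") - 1L
  definition <- paste(trimws(lines[2:def_end]), collapse = " ")
  rules <- trimws(lines[(def_end + 2L):length(lines)])
  rules <- rules[nzchar(rules)]
  examples <- switch(indicator,
    repetition = list(
      list(input = "the boy the boy falls .",
           output = '[{"type":"repetition","text":"the","span":[0,3],"span2":[8,11]},{"type":"repetition","text":"boy","span":[4,7],"span2":[12,15]}]'),
      list(input = "she washes dishes .",
           output = "[]")),
    vague = list(
      list(input = "he took the thing from the thing over there .",
           output = '[{"type":"vague","text":"thing","span":[12,17]},{"type":"vague","text":"thing","span":[27,32]}]'),
      list(input = "the cookie jar is on the shelf .",
           output = "[]")),
    list())
  prompt_spec(indicator,
              persona = paste("You are a neurologist reviewing the transcript",
                              "of a patient's speech sample for indicators of",
                              "cognitive impairment."),
              definition = definition, rules = rules,
              few_shot_examples = examples)
}

#' Render a detector prompt
#'
#' Deterministic template assembly: persona, indicator definition and rules,
#' few-shot examples (possibly none), the JSON output-format instruction, then
#' the input text verbatim. Byte-identical output for identical inputs.
#'
#' @param spec a [prompt_spec()].
#' @param input_text the utterance or transcript text to analyze (non-empty).
#' @return prompt text (character scalar).
#' @export
render_prompt <- function(spec, input_text) {
  stopifnot(inherits(spec, "prompt_spec"))
  if (!is.character(input_text) || length(input_text) != 1L ||
      !nzchar(trimws(input_text))) {
    stop("empty input text: nothing to analyze", call. = FALSE)
  }
  parts <- c(
    spec$persona,
    "",
    paste0("Indicator: ", spec$indicator),
    paste0("Definition: ", spec$definition),
    "Rules:",
    paste0("- ", spec$rules)
  )
  if (length(spec$few_shot_examples)) {
    parts <- c(parts, "", "Examples:")
    for (ex in spec$few_shot_examples) {
      parts <- c(parts, paste0("Input: ", ex$input),
                 paste0("Output: ", ex$output))
    }
  }
  parts <- c(
    parts, "",
    paste0("Respond with a JSON array of objects with keys: ",
           paste(spec$output_schema, collapse = ", "),
           ". Character spans are 0-based half-open [start, end) into the input. ",
           "Respond with [] if nothing is found."),
    "",
    paste0("Input: ", input_text),
    "Output:")
  paste(parts, collapse = "\n")
}

# locate the first balanced JSON array/object in free text (string-aware)
extract_first_json <- function(text) {
  chars <- strsplit(text, "")[[1]]
  open_at <- which(chars %in% c("[", "{"))
  if (!length(open_at)) return(NULL)
  start <- open_at[1]
  depth <- 0L; in_str <- FALSE; esc <- FALSE
  for (i in start:length(chars)) {
    ch <- chars[i]
    if (in_str) {
      if (esc) esc <- FALSE
      else if (ch == "\\") esc <- TRUE
      else if (ch == '"') in_str <- FALSE
      next
    }
    if (ch == '"') in_str <- TRUE
    else if (ch %in% c("[", "{")) depth <- depth + 1L
    else if (ch %in% c("]", "}")) {
      depth <- depth - 1L
      if (depth == 0L) return(substr(text, start, i))
    }
  }
  NULL
}

# validate one (start, end) span against the analyzed text, allowing a +-1
# repair; returns list(start, end, repaired) or NULL
validate_span <- function(span, expected_text, target_text) {
  if (!is.numeric(span) || length(span) != 2 || any(is.na(span))) return(NULL)
  s <- as.integer(span[1]); e <- as.integer(span[2])
  cands <- list(c(s, e), c(s - 1L, e - 1L), c(s + 1L, e + 1L),
                c(s, e - 1L), c(s, e + 1L), c(s - 1L, e), c(s + 1L, e))
  for (k in seq_along(cands)) {
    a <- cands[[k]][1]; b <- cands[[k]][2]
    if (a < 0 || b > nchar(target_text) || b <= a) next
    if (tolower(substring_span(target_text, a, b)) == tolower(expected_text)) {
      return(list(start = a, end = b, repaired = k > 1L))
    }
  }
  NULL
}

#' Parse and validate an LLM detector response
#'
#' Extracts the first JSON array/object in the response, validates required
#' keys against the prompt spec, and validates every reported span against the
#' analyzed text (the substring at the span must reproduce the reported text,
#' case-insensitively; an off-by-one span is repaired before being dropped).
#' Invalid entries are dropped with a reason; no parseable JSON yields an
#' empty result, never an error.
#'
#' @param response_text raw response text (may be arbitrary).
#' @param spec the [prompt_spec()] used for the request.
#' @param target_text the text that was analyzed.
#' @return detection data.frame; dropped-entry reasons and repairs are
#'   attached as attribute `"log"` (character vector).
#' @export
parse_llm_response <- function(response_text, spec, target_text) {
  stopifnot(inherits(spec, "prompt_spec"))
  log <- character()
  json <- extract_first_json(response_text)
  if (is.null(json)) {
    out <- empty_detections()
    attr(out, "log") <- "no parseable JSON in response"
    return(out)
  }
  parsed <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
                     error = function(e) NULL)
  if (is.null(parsed)) {
    out <- empty_detections()
    attr(out, "log") <- "JSON candidate failed to parse"
    return(out)
  }
  if (!is.null(names(parsed))) parsed <- list(parsed)  # single object

  required <- setdiff(spec$output_schema, "justification")
  rows <- list()
  for (i in seq_along(parsed)) {
    entry <- parsed[[i]]
    if (!is.list(entry) || !all(required %in% names(entry))) {
      log <- c(log, sprintf("entry %d: missing required keys", i)); next
    }
    sp <- validate_span(unlist(entry$span), entry$text, target_text)
    if (is.null(sp)) {
      log <- c(log, sprintf("entry %d: span/text mismatch ('%s')", i,
                            entry$text)); next
    }
    if (sp$repaired) log <- c(log, sprintf("entry %d: span repaired", i))
    s2 <- e2 <- NA_real_
    if ("span2" %in% spec$output_schema) {
      sp2 <- validate_span(unlist(entry$span2), entry$text, target_text)
      if (is.null(sp2)) {
        log <- c(log, sprintf("entry %d: span2/text mismatch", i)); next
      }
      if (sp2$start <= sp$start) {
        log <- c(log, sprintf("entry %d: span2 does not follow span", i)); next
      }
      if (sp2$repaired) log <- c(log, sprintf("entry %d: span2 repaired", i))
      s2 <- sp2$start; e2 <- sp2$end
    }
    rows[[length(rows) + 1L]] <- detection_row(
      spec$indicator, as.character(entry$text), sp$start, sp$end, s2, e2,
      justification = if (!is.null(entry$justification))
        as.character(entry$justification) else NA_character_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_detections()
  attr(out, "log") <- log
  out
}

#' Scripted mock LLM client
#'
#' Returns a client `function(prompt, input_text)` serving canned responses
#' keyed by the analyzed input text; unknown inputs get `default`. Makes the
#' full LLM detector path deterministic and network-free.
#'
#' @param responses named list/character vector: input text -> response text.
#' @param default response for inputs with no canned entry (default `"[]"`).
#' @export
llm_client_mock <- function(responses = list(), default = "[]") {
  responses <- as.list(responses)
  function(prompt, input_text) {
    if (!is.null(responses[[input_text]])) responses[[input_text]] else default
  }
}

#' Run an LLM-prompted detector over a transcript
#'
#' Filler and repetition prompts are issued once per patient utterance (spans
#' index that utterance's clean text); substitution and vague prompts see the
#' whole patient transcript at once (utterances joined with newlines; spans
#' are mapped back to utterances when they fall inside one).
#'
#' @param t a `chat_transcript`.
#' @param spec a [prompt_spec()].
#' @param client a client function `(prompt, input_text) -> response text`,
#'   e.g. [llm_client_mock()].
#' @return detection data.frame.
#' @export
llm_detect <- function(t, spec, client) {
  stopifnot(inherits(t, "chat_transcript"), inherits(spec, "prompt_spec"),
            is.function(client))
  gran <- llm_client_contract()$granularity[[spec$indicator]]
  pats <- patient_utterances(t)
  pats <- Filter(function(u) nzchar(trimws(u$clean_text)), pats)
  if (!length(pats)) return(empty_detections())

  if (gran == "utterance") {
    out <- lapply(pats, function(u) {
      prompt <- render_prompt(spec, u$clean_text)
      det <- parse_llm_response(client(prompt, u$clean_text), spec,
                                u$clean_text)
      if (nrow(det)) det$utterance_index <- u$index
      det
    })
    return(do.call(bind_detections, out))
  }

  texts <- vapply(pats, function(u) u$clean_text, character(1))
  joined <- paste(texts, collapse = "\n")
  prompt <- render_prompt(spec, joined)
  det <- parse_llm_response(client(prompt, joined), spec, joined)
  if (nrow(det)) {
    # map transcript-level spans back to utterances where possible
    offsets <- cumsum(c(0, nchar(texts) + 1L))[seq_along(texts)]
    for (r in seq_len(nrow(det))) {
      k <- findInterval(det$start[r], offsets)
      if (k >= 1 && det$end[r] <= offsets[k] + nchar(texts[k])) {
        det$utterance_index[r] <- pats[[k]]$index
        det$start[r] <- det$start[r] - offsets[k]
        det$end[r] <- det$end[r] - offsets[k]
        if (!is.na(det$start2[r])) {
          det$start2[r] <- det$start2[r] - offsets[k]
          det$end2[r] <- det$end2[r] - offsets[k]
        }
      }
    }
  }
  det
}
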