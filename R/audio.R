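#' Construct a waveform object
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]` (mono) or a matrix
#'   with one column per channel, which is downmixed to mono by channel mean.
#' @param sample_rate sampling rate in Hz.
#' @return object of class `waveform`: list with `samples` and `sample_rate`.
#' @export
waveform <- function(samples, sample_rate) {
  if (is.matrix(samples)) samples <- rowMeans(samples)
  stopifnot(is.numeric(samples), length(sample_rate) == 1L, sample_rate > 0,
            all(is.finite(samples) | length(samples) == 0L))
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %.1f ms @ %g Hz (%d samples)\n",
              1000 * length(x$samples) / x$sample_rate, x$sample_rate,
              length(x$samples)))
  invisible(x)
}

#' Duration of a waveform in milliseconds
#' @param w a `waveform`.
#' @export
duration_ms <- function(w) {
  stopifnot(inherits(w, "waveform"))
  1000 * length(w$samples) / w$sample_rate
}

#' Silence-detection configuration
#'
#' @param threshold_dbfs silence threshold in dBFS (must be negative;
#'   default -55, the high-recall operating point).
#' @param min_silence_ms minimum duration for a segment to count as silence
#'   (default 10 ms, chosen to capture all candidate pauses for downstream
#'   feature extraction).
#' @param frame_ms analysis frame length in ms (default 1).
#' @return list of class `silence_config`.
#' @export
silence_config <- function(threshold_dbfs = -55, min_silence_ms = 10,
                           frame_ms = 1) {
  stopifnot(threshold_dbfs < 0, frame_ms >= 1, min_silence_ms >= frame_ms)
  structure(list(threshold_dbfs = threshold_dbfs,
                 min_silence_ms = min_silence_ms, frame_ms = frame_ms),
            class = "silence_config")
}

#' Per-frame level in dBFS
#'
#' Splits the waveform into consecutive non-overlapping frames of `frame_ms`
#' and returns `20 * log10(RMS)` per frame; a zero-RMS frame maps to `-Inf` and
#' a full-scale constant signal to 0 dBFS. A trailing residue shorter than one
#' frame is discarded.
#'
#' @param w a `waveform`.
#' @param frame_ms frame length in milliseconds (>= 1).
#' @return numeric vector, one dBFS value per frame.
#' @export
frame_dbfs <- function(w, frame_ms = 1) {
  stopifnot(inherits(w, "waveform"), frame_ms >= 1)
  spf <- max(1L, as.integer(round(w$sample_rate * frame_ms / 1000)))
  n_frames <- length(w$samples) %/% spf
  if (n_frames == 0L) return(numeric())
  m <- matrix(w$samples[seq_len(n_frames * spf)], nrow = spf)
  rms <- sqrt(colMeans(m^2))
  ifelse(rms > 0, 20 * log10(rms), -Inf)
}

#' Detect silent segments in a waveform
#'
#' Returns maximal runs of consecutive frames whose level is at or below
#' `cfg$threshold_dbfs` and whose total duration is at least
#' `cfg$min_silence_ms`. Boundaries are quantized to the frame length.
#'
#' @param w a `waveform` (duration must be at least one frame).
#' @param cfg a [silence_config()].
#' @return data.frame with columns `start_ms`, `end_ms`, sorted and
#'   non-overlapping (zero rows when nothing qualifies).
#' @export
detect_silences <- function(w, cfg = silence_config()) {
  stopifnot(inherits(w, "waveform"), inherits(cfg, "silence_config"))
  lev <- frame_dbfs(w, cfg$frame_ms)
  if (!length(lev)) return(empty_segments())
  silent <- lev <= cfg$threshold_dbfs
  r <- rle(silent)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * cfg$frame_ms >= cfg$min_silence_ms)
  if (!any(keep)) return(empty_segments())
  data.frame(start_ms = (starts[keep] - 1L) * cfg$frame_ms,
             end_ms = ends[keep] * cfg$frame_ms)
}

empty_segments <- function() {
  data.frame(start_ms = numeric(), end_ms = numeric())
}

#' Filter silences down to speech delays
#'
#' Keeps only segments at least `min_delay_ms` long. Raising the cutoff makes
#' the detector more conservative (precision up, recall down); 1950 ms is the
#' F1-optimal operating point reported for picture-description speech.
#'
#' @param silences data.frame of segments (`start_ms`, `end_ms`), sorted and
#'   non-overlapping.
#' @param min_delay_ms minimum duration in ms.
#' @return the qualifying subset, same columns.
#' @export
speech_delay_segments <- function(silences, min_delay_ms = 1950) {
  stopifnot(is.data.frame(silences),
            all(c("start_ms", "end_ms") %in% names(silences)))
  silences[silences$end_ms - silences$start_ms >= min_delay_ms, , drop = FALSE]
}

#' Serialize silence segments to JSON
#' @param silences data.frame of segments.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
silences_to_json <- function(silences, path = NULL) {
  pairs <- unname(mapply(function(s, e) c(s, e), silences$start_ms,
                         silences$end_ms, SIMPLIFY = FALSE))
  if (is.null(path)) return(jsonlite::toJSON(pairs, digits = NA))
  jsonlite::write_json(pairs, path, digits = NA)
  invisible(path)
}

# ---- WAV I/O (PCM integer 16/24/32-bit and IEEE float32) -------------------

#' Read a mono or stereo WAV file
#'
#' Supports PCM 16/24/32-bit integer and 32-bit IEEE float. Multi-channel
#' input is downmixed to mono by channel mean.
#'
#' @param path WAV file path.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id) || length(id) == 0L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("incomplete WAV file: ", path)

  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", length(data_raw) / 4, 4,
                 endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 32L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 4, 4,
                 endian = "little") / 2147483648
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    b <- as.integer(data_raw)
    n <- length(b) %/% 3
    v <- b[seq(1, by = 3, length.out = n)] +
      256 * b[seq(2, by = 3, length.out = n)] +
      65536 * b[seq(3, by = 3, length.out = n)]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d-bit)",
                 fmt$audio_format, fmt$bits))
  }
  if (fmt$n_channels > 1L) {
    x <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
  }
  waveform(x, fmt$sample_rate)
}

#' Write a waveform as 16-bit PCM WAV
#'
#' @param w a [waveform()]; samples are clipped to `[-1, 1]`.
#' @param path output file path.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmax(-1, pmin(1, w$samples))
  pcm <- as.integer(pmin(32767, round(x * 32768)))
  n <- length(pcm)
  sr <- as.integer(round(w$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")        # PCM
  writeBin(1L, con, 2, endian = "little")        # mono
  writeBin(sr, con, 4, endian = "little")
  writeBin(as.integer(sr * 2), con, 4, endian = "little")  # byte rate
  writeBin(2L, con, 2, endian = "little")        # block align
  writeBin(16L, con, 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
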