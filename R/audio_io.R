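#' Construct an audio clip
#'
#' An `audio_clip` holds a mono amplitude sequence in `[-1, 1]` together with
#' its sample rate in Hz and an opaque source identifier (typically the
#' participant id). All downstream feature extraction takes its rate from the
#' clip, never from an assumed constant.
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`, length >= 1.
#' @param sample_rate Sampling rate in samples/second, > 0.
#' @param source_id Optional identifier carried through the pipeline.
#' @return An object of class `audio_clip` with fields `samples`,
#'   `sample_rate`, `source_id`.
#' @export
audio_clip <- function(samples, sample_rate, source_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio_clip: samples must have length >= 1")
  if (!all(is.finite(samples))) stop("audio_clip: samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("audio_clip: sample_rate must be a single positive number")
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         source_id = as.character(source_id)),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s: %d samples @ %g Hz (%.3f s)\n",
              x$source_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

# --- minimal RIFF/PCM WAV codec -------------------------------------------
# No audio package is assumed; the format is plain RIFF with a "fmt " chunk
# (PCM, format tag 1) and a "data" chunk. Integer PCM is scaled symmetrically
# by the max positive code (e.g. 32767 for 16-bit) in both directions so the
# write->read round trip errs by at most half a quantisation step.

.wav_scale <- function(bits) 2^(bits - 1) - 1

#' Read a PCM WAV file
#'
#' Reads a RIFF/PCM WAV file (8/16/24/32-bit integer PCM). Multichannel
#' recordings are down-mixed to mono by the channel mean. Amplitudes are
#' scaled to `[-1, 1]`; the sample rate is taken from the file header.
#'
#' @param path Path to a `.wav` file.
#' @param source_id Identifier stored on the returned clip; defaults to the
#'   file name without extension.
#' @return An [audio_clip].
#' @export
read_wav <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("read_wav: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE payload: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format   = sum(as.integer(body[1:2]) * c(1L, 256L)),
        channels = sum(as.integer(body[3:4]) * c(1L, 256L)),
        rate     = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits     = sum(as.integer(body[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("read_wav: missing fmt/data chunk in ", path)
  }
  if (fmt$format != 1L) stop("read_wav: only integer PCM (format 1) supported")
  if (length(data_raw) == 0L) stop("read_wav: zero-length data stream in ", path)

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  x <- if (fmt$bits == 8L) {
    # 8-bit WAV is unsigned, offset binary
    as.numeric(readBin(data_raw, "integer", n_total, size = 1L, signed = FALSE)) - 128
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n_total * 3L)]), nrow = 3L)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    ifelse(v >= 2^23, v - 2^24, v)
  } else {
    as.numeric(readBin(data_raw, "integer", n_total, size = bytes,
                       signed = TRUE, endian = "little"))
  }
  scale <- if (fmt$bits == 8L) 127 else .wav_scale(fmt$bits)
  x <- x / scale
  if (fmt$channels > 1L) {
    n_frames <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$channels)],
                         nrow = fmt$channels))
  }
  x <- pmin(1, pmax(-1, x))
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  audio_clip(x, fmt$rate, source_id)
}

#' Write an audio clip as 16-bit PCM WAV
#'
#' @param clip An [audio_clip] with samples in `[-1, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  if (any(abs(clip$samples) > 1)) {
    stop("write_wav: samples outside [-1, 1]")
  }
  scale <- .wav_scale(16L)
  pcm <- as.integer(round(clip$samples * scale))
  n_bytes <- length(pcm) * 2L
  rate <- as.integer(round(clip$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(1L, con, size = 2L, endian = "little")          # mono
  writeBin(rate, con, size = 4L, endian = "little")
  writeBin(rate * 2L, con, size = 4L, endian = "little")   # byte rate
  writeBin(2L, con, size = 2L, endian = "little")          # block align
  writeBin(16L, con, size = 2L, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Truncate a clip to a time window
#'
#' Mirrors the manual trimming of recordings to the participant's voice:
#' keeps samples in `[start_s, end_s)`. The returned length is
#' `round((end_s - start_s) * sample_rate)` and the rate is unchanged.
#'
#' @param clip An [audio_clip].
#' @param start_s,end_s Window bounds in seconds,
#'   `0 <= start_s < end_s <= duration`.
#' @return The truncated [audio_clip].
#' @export
truncate_clip <- function(clip, start_s, end_s) {
  stopifnot(inherits(clip, "audio_clip"))
  dur <- clip_duration(clip)
  if (start_s < 0 || end_s > dur + 1e-9 || start_s >= end_s) {
    stop("truncate_clip: need 0 <= start_s < end_s <= duration")
  }
  n <- round((end_s - start_s) * clip$sample_rate)
  i0 <- round(start_s * clip$sample_rate)
  i0 <- min(i0, length(clip$samples) - n)
  audio_clip(clip$samples[(i0 + 1L):(i0 + n)], clip$sample_rate,
             clip$source_id)
}

# --- participant manifest --------------------------------------------------

#' Read a participant manifest
#'
#' A manifest is a headed CSV with columns `participant_id`, `label`
#' (0 = control, 1 = mTBI), `clip_path`. Ids must be unique.
#'
#' @param path CSV path.
#' @return A data.frame with the three columns.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

#' Write a participant manifest
#' @param manifest Data.frame with `participant_id`, `label`, `clip_path`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Validate a participant manifest
#' @param manifest Data.frame to check.
#' @return The manifest, invisibly-validated (columns coerced).
#' @export
validate_manifest <- function(manifest) {
  need <- c("participant_id", "label", "clip_path")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  manifest$participant_id <- as.character(manifest$participant_id)
  manifest$label <- as.integer(manifest$label)
  if (anyDuplicated(manifest$participant_id)) {
    stop("manifest: participant_id values must be unique")
  }
  if (!all(manifest$label %in% c(0L, 1L))) {
    stop("manifest: label must be 0 (control) or 1 (mTBI)")
  }
  manifest
}
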