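#' Audio rendering parameters
#'
#' @param sample_rate Sampling rate in Hz.
#' @param amplitude Peak amplitude as a fraction of full scale (no note
#'   ever exceeds it, so the render cannot clip).
#' @param fade_ms Linear fade-in/out at each note boundary, in milliseconds,
#'   to avoid clicks.
#' @param seconds_per_whole_note Seconds one whole note lasts. `NULL` takes
#'   the convention stored in the melody set (1 s for standard melodies; 4 s
#'   for recalibrated ones, where a crotchet lasts 1 s).
#' @return An object of class `"audio_spec"`.
#' @export
audio_spec <- function(sample_rate = 44100, amplitude = 0.8, fade_ms = 5,
                       seconds_per_whole_note = NULL) {
  stopifnot(is.numeric(sample_rate), sample_rate > 0,
            is.numeric(amplitude), amplitude > 0, amplitude <= 1,
            is.numeric(fade_ms), fade_ms >= 0)
  structure(list(sample_rate = as.integer(sample_rate),
                 amplitude = amplitude, fade_ms = fade_ms,
                 seconds_per_whole_note = seconds_per_whole_note),
            class = "audio_spec")
}

#' Notes of one melody as frequency/duration pairs
#'
#' @param ms A `melody_set`.
#' @param sample A sample id or `"median"`.
#' @return data.frame with `frequency_hz` and `duration_s` columns.
#' @export
melody_notes <- function(ms, sample) {
  stopifnot(inherits(ms, "melody_set"))
  check_sample(ms, sample)
  data.frame(frequency_hz = unname(ms$frequency[, sample]),
             duration_s = ms$duration$fraction * ms$seconds_per_whole_note)
}

# Sine synthesis of one channel. Each note gets round(duration * rate)
# frames, so total length differs from round(sum * rate) by at most one
# frame per note boundary.
synth_channel <- function(frequency_hz, duration_s, spec) {
  if (!length(frequency_hz)) stop("empty melody")
  stopifnot(length(frequency_hz) == length(duration_s))
  if (any(frequency_hz <= 0)) stop("all frequencies must be positive")
  if (any(duration_s <= 0)) stop("all durations must be positive")
  sr <- spec$sample_rate
  pieces <- vector("list", length(frequency_hz))
  for (i in seq_along(frequency_hz)) {
    n <- round(duration_s[i] * sr)
    t <- (seq_len(n) - 1) / sr
    x <- spec$amplitude * sin(2 * pi * frequency_hz[i] * t)
    nf <- min(round(spec$fade_ms / 1000 * sr), n %/% 2)
    if (nf > 0) {
      ramp <- seq_len(nf) / nf
      x[seq_len(nf)] <- x[seq_len(nf)] * ramp
      x[n - nf + seq_len(nf)] <- x[n - nf + seq_len(nf)] * rev(ramp)
    }
    pieces[[i]] <- x
  }
  unlist(pieces)
}

resolve_notes <- function(melody, sample, spec) {
  if (inherits(melody, "melody_set")) {
    if (is.null(sample)) stop("a sample id is required for a melody_set")
    notes <- melody_notes(melody, sample)
    if (!is.null(spec$seconds_per_whole_note)) {
      notes$duration_s <- melody$duration$fraction *
        spec$seconds_per_whole_note
    }
    notes
  } else {
    stopifnot(is.data.frame(melody),
              all(c("frequency_hz", "duration_s") %in% names(melody)))
    melody
  }
}

#' Render a melody to a mono WAV file
#'
#' Each note is a pure sine tone at its frequency, lasting its duration
#' times the seconds-per-whole-note convention, with short linear fades at
#' the boundaries; notes are concatenated. Output is 16-bit integer PCM.
#' Rendering is deterministic: the same melody and spec give byte-identical
#' files.
#'
#' @param melody A `melody_set` (with `sample`) or a data.frame with
#'   `frequency_hz` and `duration_s` columns.
#' @param sample Sample id or `"median"` when `melody` is a `melody_set`.
#' @param spec An [audio_spec()].
#' @param path Output `.wav` path.
#' @return `path`, invisibly.
#' @export
render_wav <- function(melody, sample = NULL, spec = audio_spec(), path) {
  notes <- resolve_notes(melody, sample, spec)
  x <- synth_channel(notes$frequency_hz, notes$duration_s, spec)
  write_wav(matrix(x, ncol = 1L), spec$sample_rate, path)
}

#' Render a sample against the median as a stereo WAV file
#'
#' One channel carries the median reference melody, the other the sample's
#' melody (median on the left by default). Aligned notes share durations,
#' so both channels have identical length and stay note-for-note in sync.
#'
#' @param ms A `melody_set`.
#' @param sample A sample id.
#' @param spec An [audio_spec()].
#' @param path Output `.wav` path.
#' @param median_channel `"left"` or `"right"`.
#' @return `path`, invisibly.
#' @export
render_stereo <- function(ms, sample, spec = audio_spec(), path,
                          median_channel = c("left", "right")) {
  stopifnot(inherits(ms, "melody_set"))
  median_channel <- match.arg(median_channel)
  med <- resolve_notes(ms, "median", spec)
  smp <- resolve_notes(ms, sample, spec)
  med_x <- synth_channel(med$frequency_hz, med$duration_s, spec)
  smp_x <- synth_channel(smp$frequency_hz, smp$duration_s, spec)
  chans <- if (median_channel == "left") cbind(med_x, smp_x)
           else cbind(smp_x, med_x)
  write_wav(chans, spec$sample_rate, path)
}

# RIFF/WAVE PCM writer: 16-bit little-endian signed integer samples.
# `samples` is a frames x channels matrix of values in [-1, 1].
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.matrix(samples))
  n_chan <- ncol(samples)
  ints <- as.integer(round(pmin(pmax(t(samples), -1), 1) * 32767))
  data_size <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(n_chan, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_chan * 2L), con, size = 4,
           endian = "little")
  writeBin(as.integer(n_chan * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")      # interleaved
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Minimal chunk-walking reader for the files this package writes (and any
#' canonical 16-bit PCM RIFF file).
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (frames x channels matrix in `[-1, 1]`),
#'   `sample_rate` and `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file")
  }
  n_chan <- NULL; sr <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || !nzchar(id)) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      n_chan <- fmt[2L]
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) readBin(con, raw(), n = extra)
    } else if (identical(id, "data")) {
      if (bits != 16L) stop("only 16-bit PCM is supported")
      data <- readBin(con, integer(), n = size %/% 2L, size = 2,
                      endian = "little")
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(data)) stop("no data chunk found")
  list(samples = matrix(data / 32767, ncol = n_chan, byrow = TRUE),
       sample_rate = sr, bits = bits)
}
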