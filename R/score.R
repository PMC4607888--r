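#' Export a melody as a LilyPond score
#'
#' Writes plain-text music notation (LilyPond syntax, absolute pitch mode)
#' for one channel of a melody set. Standard notation exists only for
#' 12-step octaves; other tunings are rejected. Recalibrated melodies carry
#' continuous frequencies and are snapped to the nearest key first. The
#' clef is chosen per melody: bass when more than half of the notes lie
#' below middle C, treble otherwise.
#'
#' @param ms A `melody_set`.
#' @param sample A sample id or `"median"`.
#' @param path Output `.ly` path.
#' @param clef `"auto"` (default rule above), `"treble"` or `"bass"`.
#' @return `path`, invisibly.
#' @export
export_score <- function(ms, sample, path, clef = "auto") {
  stopifnot(inherits(ms, "melody_set"))
  check_sample(ms, sample)
  if (ms$tuning$steps_per_octave != 12L) {
    stop("score export requires 12 steps per octave (standard notation)")
  }
  if (!length(ms$probe_ids)) stop("empty melody")
  freq <- ms$frequency[, sample]
  key <- suppressWarnings(frequency_to_key(freq, ms$tuning))
  midi <- round(69 + 12 * log2(key_to_frequency(key, ms$tuning) / 440))
  if (clef == "auto") {
    clef <- if (mean(midi < 60) > 0.5) "bass" else "treble"
  }
  dur <- ms$duration
  tokens <- vapply(seq_along(midi), function(i) {
    paste0(midi_to_lily(midi[i]),
           duration_to_lily(dur$principal[i], dur$dots[i], dur$fraction[i]))
  }, character(1L))
  lines <- c("\\version \"2.24.0\"",
             sprintf("%% melody: %s (%d notes)", sample, length(tokens)),
             "{",
             sprintf("  \\clef %s", clef),
             paste0("  ", paste(tokens, collapse = " ")),
             "}")
  writeLines(lines, path)
  invisible(path)
}

# MIDI note number -> LilyPond absolute pitch (c' = middle C = MIDI 60).
midi_to_lily <- function(midi) {
  names12 <- c("c", "cis", "d", "dis", "e", "f", "fis", "g", "gis", "a",
               "ais", "b")
  pc <- midi %% 12L
  oct <- midi %/% 12L - 1L  # scientific octave; LilyPond c == C3
  marks <- oct - 3L
  paste0(names12[pc + 1L],
         if (marks > 0) strrep("'", marks) else strrep(",", -marks))
}

duration_to_lily <- function(principal, dots, fraction) {
  if (is.na(principal)) {
    # inexpressible template duration: nearest principal, no dots
    principal <- 2^round(log2(fraction))
    principal <- min(max(principal, 1 / 64), 1)
    dots <- 0L
  }
  paste0(format(round(1 / principal)), strrep(".", dots))
}

#' Plot frequency or divergence courses
#'
#' Frequency mode draws each requested sample's frequency course as a step
#' line together with the median reference. Divergence mode draws per-note
#' absolute differences to the median with the ordinary-least-squares trend
#' line of each sample. The image format follows the file extension
#' (`.png` or `.svg`).
#'
#' @param ms A `melody_set`.
#' @param samples Character vector of sample ids (default: all real
#'   samples).
#' @param mode `"frequency"` or `"divergence"`.
#' @param path Output image path.
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return `path`, invisibly.
#' @export
plot_courses <- function(ms, samples = ms$sample_ids,
                         mode = c("frequency", "divergence"), path,
                         width = NULL, height = NULL) {
  stopifnot(inherits(ms, "melody_set"))
  mode <- match.arg(mode)
  for (s in samples) check_sample(ms, s)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    grDevices::png(path, width = width %||% 900, height = height %||% 600)
  } else if (ext == "svg") {
    grDevices::svg(path, width = width %||% 9, height = height %||% 6)
  } else {
    stop(sprintf("unsupported image extension '.%s' (use .png or .svg)", ext))
  }
  on.exit(grDevices::dev.off())
  cols <- grDevices::hcl.colors(max(length(samples), 2L), "Dark 3")
  if (mode == "frequency") {
    courses <- lapply(c(samples, "median"), function(s) frequency_course(ms, s))
    ylim <- range(vapply(courses, function(d) range(d$frequency_hz),
                         numeric(2L)))
    graphics::plot(NA, xlim = range(courses[[1L]]$time_s), ylim = ylim,
         xlab = "time (s)", ylab = "frequency (Hz)")
    for (i in seq_along(samples)) {
      graphics::lines(courses[[i]], type = "s", col = cols[i])
    }
    graphics::lines(courses[[length(courses)]], type = "s", col = "black",
                    lwd = 2, lty = 2)
    graphics::legend("topleft", legend = c(samples, "median"),
                     col = c(cols[seq_along(samples)], "black"),
                     lty = c(rep(1, length(samples)), 2), bty = "n")
  } else {
    divs <- lapply(samples, function(s) divergence_course(ms, s))
    ylim <- range(0, vapply(divs, function(d) max(d$course$abs_diff_hz),
                            numeric(1L)))
    graphics::plot(NA, xlim = range(divs[[1L]]$course$time_s), ylim = ylim,
         xlab = "time (s)", ylab = "|frequency - median| (Hz)")
    for (i in seq_along(divs)) {
      graphics::points(divs[[i]]$course, col = cols[i], pch = 16, cex = 0.6)
      graphics::abline(divs[[i]]$intercept, divs[[i]]$slope, col = cols[i])
    }
    graphics::legend("topright", legend = samples,
                     col = cols[seq_along(samples)], lty = 1, bty = "n")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
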