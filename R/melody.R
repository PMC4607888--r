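#' Keep the probe sets with the most variable frequencies
#'
#' Transforms the matrix to frequencies (each sample scaled by its own
#' maximum over all probes), ranks probes by the sample variance of those
#' frequencies, and returns the submatrix of the top `k` probes in their
#' original row order. The variance of the `(k+1)`-th ranked probe is
#' retained as the `s2_min` of the selection context, so every kept probe
#' has variance strictly above it; the maximum is retained as `s2_max`.
#'
#' @param matrix Numeric log2 matrix, probes in rows, >= 2 samples.
#' @param tuning A [tuning()].
#' @param k Number of probes to keep, or a fraction in (0, 1] of all probes
#'   (rounded up).
#' @return The submatrix, with attributes `variances` (per kept probe, in
#'   row order), `s2_min` and `s2_max`.
#' @export
variance_filter <- function(matrix, tuning = sonifex::tuning(), k) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 2L) stop("variance filtering needs >= 2 samples")
  n <- nrow(matrix)
  stopifnot(is.numeric(k), length(k) == 1L, k > 0)
  if (k < 1) k <- ceiling(k * n)
  k <- as.integer(k)
  if (k > n) stop(sprintf("k = %d exceeds probe count %d", k, n))
  freq <- frequency_matrix(matrix, tuning)
  v <- apply(freq, 1L, stats::var)
  ord <- order(-v)  # stable: ties keep input order
  keep <- sort(ord[seq_len(k)])  # original relative probe order
  s2_min <- if (k < n) v[ord[k + 1L]] else min(v)
  out <- matrix[keep, , drop = FALSE]
  attr(out, "variances") <- v[keep]
  attr(out, "s2_min") <- s2_min
  attr(out, "s2_max") <- max(v)
  out
}

#' Default number of tones for a data set
#'
#' The convention `steps_per_octave x number_of_principal_lengths x
#' n_samples`: with 12 semitone steps and 4 principal lengths this gives
#' 192 tones for 4 samples and 288 for 6.
#'
#' @param n_samples Number of samples.
#' @param tuning A [tuning()].
#' @param spec A [rhythm_spec()].
#' @return Integer tone count.
#' @examples
#' default_tone_count(4)  # 192
#' @export
default_tone_count <- function(n_samples, tuning = sonifex::tuning(),
                               spec = rhythm_spec()) {
  stopifnot(is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 1)
  as.integer(tuning$steps_per_octave * length(spec$principal_lengths) *
               n_samples)
}

#' Probe order by ascending median frequency
#'
#' The median pseudo-sample's intensities are transformed into frequencies
#' (using the median profile's own maximum as scaling) and probes are sorted
#' ascending by that frequency. The sort is stable: probes with equal median
#' frequency keep their input order. Probes over-expressed in outliers
#' relative to the median tend to land at the start of the melody, and
#' under-expressed ones at the end.
#'
#' @param matrix Numeric log2 matrix, probes in rows.
#' @param tuning A [tuning()].
#' @return Integer permutation of row indices.
#' @export
sort_by_median <- function(matrix, tuning = sonifex::tuning()) {
  validate_expression_matrix(matrix)
  med <- median_profile(matrix)
  sc <- sample_scaling("median", max(med))
  f <- key_to_frequency(compute_key(med, sc, tuning), tuning)
  order(f)  # stable
}

#' Build an aligned melody set from an expression matrix
#'
#' The full sonification pipeline:
#' 1. [variance_filter()] keeps the `k` probes with the most variable
#'    frequencies (variances computed with whole-matrix scaling) and records
#'    the variance context (`s2_min` from the `(k+1)`-th probe, `s2_max`).
#' 2. Keys and frequencies are recomputed for the kept probes, each sample
#'    scaled by the maximum intensity of its analysed (post-filter) probes.
#' 3. Durations are assigned per probe from the variance context via
#'    [duration_from_variance()]; aligned notes share one duration across
#'    samples.
#' 4. A median pseudo-sample is appended, scaled by its own maximum; it is a
#'    sorting and comparison reference and takes no part in variances or in
#'    the scaling of real samples.
#' 5. All melodies are jointly reordered by [sort_by_median()], so the
#'    median melody is non-decreasing in frequency over time.
#'
#' @param matrix Numeric log2 matrix, probes in rows, >= 2 samples.
#' @param tuning A [tuning()].
#' @param spec A [rhythm_spec()].
#' @param k Tone count; `NULL` uses [default_tone_count()]. Must be at most
#'   `nrow(matrix) - 1` so the `(k+1)`-th variance exists.
#' @return An object of class `"melody_set"`: list with `probe_ids`,
#'   `sample_ids`, `key` and `frequency` matrices (one column per sample
#'   plus `"median"`), a `duration` data.frame (`principal`, `dots`,
#'   `fraction`), `variance`, `tuning`, `rhythm`, `seconds_per_whole_note`
#'   and provenance fields.
#' @export
build_melody_set <- function(matrix, tuning = sonifex::tuning(),
                             spec = rhythm_spec(), k = NULL) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 2L) stop("a melody set needs >= 2 samples")
  if (is.null(k)) k <- default_tone_count(ncol(matrix), tuning, spec)
  if (is.numeric(k) && length(k) == 1L && k >= 1 && k > nrow(matrix) - 1L) {
    stop(sprintf("k = %d needs at least k + 1 = %d probes (got %d)",
                 as.integer(k), as.integer(k) + 1L, nrow(matrix)))
  }
  sub <- variance_filter(matrix, tuning, k)
  s2 <- attr(sub, "variances")
  ctx <- list(s2_min = attr(sub, "s2_min"), s2_max = attr(sub, "s2_max"))

  samples <- colnames(sub)
  keys <- matrix(NA_integer_, nrow(sub), length(samples) + 1L,
                 dimnames = list(rownames(sub), c(samples, "median")))
  for (s in samples) {
    sc <- sample_scaling(s, max(sub[, s]))
    keys[, s] <- compute_key(sub[, s], sc, tuning)
  }
  med <- median_profile(sub)
  keys[, "median"] <- compute_key(med, sample_scaling("median", max(med)),
                                  tuning)
  freq <- key_to_frequency(keys, tuning)
  dim(freq) <- dim(keys); dimnames(freq) <- dimnames(keys)

  dur <- duration_from_variance(s2, ctx$s2_min, ctx$s2_max, spec)

  ord <- order(freq[, "median"])  # stable; equals sort_by_median(sub, tuning)
  structure(list(probe_ids = rownames(sub)[ord],
                 sample_ids = samples,
                 key = keys[ord, , drop = FALSE],
                 frequency = freq[ord, , drop = FALSE],
                 duration = dur[ord, , drop = FALSE],
                 variance = s2[ord],
                 tuning = tuning,
                 rhythm = spec,
                 seconds_per_whole_note = 1,
                 recalibrated = FALSE,
                 template = NULL,
                 provenance = list(k = length(s2),
                                   n_probes_input = nrow(matrix),
                                   s2_min = ctx$s2_min,
                                   s2_max = ctx$s2_max)),
            class = "melody_set")
}

#' @export
print.melody_set <- function(x, ...) {
  cat(sprintf("<melody_set> %d notes x %d samples (+ median)%s\n",
              length(x$probe_ids), length(x$sample_ids),
              if (x$recalibrated) {
                sprintf(", recalibrated to '%s'", x$template)
              } else ""))
  cat(sprintf("  tuning: f_min %g Hz, %d keys, %d steps/octave; total %s s per melody\n",
              x$tuning$f_min, x$tuning$n_keys, x$tuning$steps_per_octave,
              format(sum(x$duration$fraction) * x$seconds_per_whole_note)))
  invisible(x)
}

melody_channels <- function(ms) c(ms$sample_ids, "median")

check_sample <- function(ms, sample) {
  if (!sample %in% melody_channels(ms)) {
    stop(sprintf("unknown sample '%s' (have: %s)", sample,
                 paste(melody_channels(ms), collapse = ", ")))
  }
  sample
}

#' Long-format notes table of a melody set
#'
#' @param x A `melody_set`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data.frame with columns `probe_id`, `sample_id`, `key`,
#'   `frequency_hz`, `duration_fraction`, `dots`, `onset_s`; one row per
#'   (note, channel) including the median channel.
#' @export
as.data.frame.melody_set <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  onset <- note_onsets(x)
  chans <- melody_channels(x)
  do.call(rbind, lapply(chans, function(s) {
    data.frame(probe_id = x$probe_ids,
               sample_id = s,
               key = x$key[, s],
               frequency_hz = x$frequency[, s],
               duration_fraction = fraction_string(x$duration$fraction),
               dots = x$duration$dots,
               onset_s = onset,
               row.names = NULL)
  }))
}

note_onsets <- function(ms) {
  d <- ms$duration$fraction * ms$seconds_per_whole_note
  cumsum(c(0, d[-length(d)]))
}

#' Frequency course of one melody
#'
#' One point per note at its onset: time is the cumulative sum of the
#' preceding durations times the seconds-per-whole-note convention of the
#' melody set (1 s by default; 4 s for recalibrated sets, where a crotchet
#' lasts 1 s).
#'
#' @param ms A `melody_set`.
#' @param sample A sample id or `"median"`.
#' @return data.frame with columns `time_s`, `frequency_hz`.
#' @export
frequency_course <- function(ms, sample) {
  stopifnot(inherits(ms, "melody_set"))
  check_sample(ms, sample)
  data.frame(time_s = note_onsets(ms),
             frequency_hz = unname(ms$frequency[, sample]))
}

#' Divergence of one melody from the median
#'
#' Per-note absolute frequency difference to the median channel, with the
#' ordinary-least-squares linear trend over onset time.
#'
#' @param ms A `melody_set`.
#' @param sample A sample id.
#' @return List with `course` (data.frame `time_s`, `abs_diff_hz`), `slope`
#'   (Hz/s) and `intercept` (Hz).
#' @export
divergence_course <- function(ms, sample) {
  stopifnot(inherits(ms, "melody_set"))
  check_sample(ms, sample)
  time_s <- note_onsets(ms)
  d <- abs(ms$frequency[, sample] - ms$frequency[, "median"])
  fit <- stats::lm(d ~ time_s)
  list(course = data.frame(time_s = time_s, abs_diff_hz = unname(d)),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]))
}

#' Count high-pitched notes per probe
#'
#' In absolute mode a note is "high" when its frequency exceeds `threshold`
#' (default 987 Hz, B5). In relative mode a note is high when its frequency
#' is at least twice (one octave above) the median channel's frequency for
#' that probe. The median channel itself is never counted.
#'
#' @param ms A `melody_set`.
#' @param threshold Absolute frequency threshold in Hz.
#' @param relative If `TRUE`, use the octave-above-median criterion instead
#'   of the absolute threshold.
#' @return List with `counts` (named integer per probe: in how many samples
#'   it is high) and `histogram` (table over "high in exactly m samples",
#'   m = 0..n_samples; bins sum to the probe count).
#' @export
count_high_pitch <- function(ms, threshold = 987, relative = FALSE) {
  stopifnot(inherits(ms, "melody_set"))
  fm <- ms$frequency[, ms$sample_ids, drop = FALSE]
  if (relative) {
    high <- fm >= 2 * ms$frequency[, "median"]
  } else {
    stopifnot(is.numeric(threshold), threshold > 0)
    high <- fm > threshold
  }
  counts <- as.integer(rowSums(high))
  names(counts) <- ms$probe_ids
  hist <- table(factor(counts, levels = 0:length(ms$sample_ids)))
  list(counts = counts, histogram = hist)
}
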