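#' Virtual keyboard tuning
#'
#' Defines the equal-temperament keyboard onto which signal intensities are
#' projected. The defaults model a standard 88-key piano: lowest key at
#' 27.5 Hz (A0) and 12 identical semitone steps per octave, so that key 49
#' sounds 440 Hz (A4). Alternative divisions of the octave (quarter-tone
#' `steps_per_octave = 24`, whole-tone `steps_per_octave = 6`) are supported
#' throughout the pitch pipeline.
#'
#' @param f_min Frequency of the lowest key, in Hz. Must be positive.
#' @param n_keys Number of keys (distinct frequencies) on the keyboard.
#' @param steps_per_octave Number of equal logarithmic steps per octave.
#' @return An object of class `"tuning"`.
#' @examples
#' key_to_frequency(49, tuning())  # 440
#' @export
tuning <- function(f_min = 27.5, n_keys = 88L, steps_per_octave = 12L) {
  stopifnot(is.numeric(f_min), length(f_min) == 1L, is.finite(f_min),
            is.numeric(n_keys), length(n_keys) == 1L,
            is.numeric(steps_per_octave), length(steps_per_octave) == 1L)
  if (f_min <= 0) stop("f_min must be positive")
  n_keys <- as.integer(n_keys)
  steps_per_octave <- as.integer(steps_per_octave)
  if (n_keys < 1L) stop("n_keys must be >= 1")
  if (steps_per_octave < 1L) stop("steps_per_octave must be >= 1")
  structure(list(f_min = f_min, n_keys = n_keys,
                 steps_per_octave = steps_per_octave),
            class = "tuning")
}

#' @export
print.tuning <- function(x, ...) {
  cat(sprintf("<tuning> f_min = %g Hz, %d keys, %d steps/octave\n",
              x$f_min, x$n_keys, x$steps_per_octave))
  invisible(x)
}

#' Per-sample intensity scaling
#'
#' Holds the maximal log2 signal intensity of the analysed probe sets of one
#' sample. Keys are computed relative to this maximum so that every sample
#' uses the full keyboard; it must be recomputed after any probe filtering
#' step.
#'
#' @param sample_id Identifier of the sample (used in error messages).
#' @param si_max Maximal log2 signal intensity among the analysed probe sets
#'   of the sample; must be positive for the key computation to be defined.
#' @return An object of class `"sample_scaling"`.
#' @export
sample_scaling <- function(sample_id, si_max) {
  stopifnot(length(sample_id) == 1L, is.numeric(si_max), length(si_max) == 1L,
            is.finite(si_max))
  structure(list(sample_id = as.character(sample_id), si_max = si_max),
            class = "sample_scaling")
}

#' Map a signal intensity to a virtual key
#'
#' The intensity is divided by `si_max / n_keys` and rounded up to the next
#' whole number, so the sample's maximal intensity lands on the top key.
#' Values at or below zero (possible after log2 transformation of weak
#' signals) clamp to key 1 rather than producing a non-positive key.
#'
#' @param si Numeric vector of log2 signal intensities.
#' @param scaling A [sample_scaling()] with positive `si_max`.
#' @param tuning A [tuning()].
#' @return Integer vector of key indices in `[1, n_keys]`.
#' @export
compute_key <- function(si, scaling, tuning = sonifex::tuning()) {
  stopifnot(inherits(scaling, "sample_scaling"), inherits(tuning, "tuning"))
  if (scaling$si_max <= 0) {
    stop(sprintf("sample '%s': si_max must be positive (got %g)",
                 scaling$sample_id, scaling$si_max))
  }
  key <- ceiling(si / (scaling$si_max / tuning$n_keys))
  as.integer(pmin(pmax(key, 1), tuning$n_keys))
}

#' Frequency of a virtual key
#'
#' Equal temperament: `f = f_min * 2^((key - 1) / steps_per_octave)`, so key
#' `k + steps_per_octave` sounds exactly one octave above key `k`.
#'
#' @param key Integer vector of key indices in `[1, n_keys]`.
#' @param tuning A [tuning()].
#' @return Numeric vector of frequencies in Hz.
#' @export
key_to_frequency <- function(key, tuning = sonifex::tuning()) {
  stopifnot(inherits(tuning, "tuning"), is.numeric(key))
  if (any(key < 1 | key > tuning$n_keys)) {
    stop(sprintf("key out of range [1, %d]", tuning$n_keys))
  }
  tuning$f_min * 2^((key - 1) / tuning$steps_per_octave)
}

#' Nearest virtual key for a frequency
#'
#' Inverse of [key_to_frequency()]: the key whose frequency is nearest in
#' log-frequency distance. Frequencies below the bottom or above the top of
#' the keyboard clamp to key 1 or `n_keys` with a warning.
#'
#' @param f Numeric vector of positive frequencies in Hz.
#' @param tuning A [tuning()].
#' @return Integer vector of key indices.
#' @export
frequency_to_key <- function(f, tuning = sonifex::tuning()) {
  stopifnot(inherits(tuning, "tuning"), is.numeric(f))
  if (any(f <= 0)) stop("frequencies must be positive")
  kr <- log2(f / tuning$f_min) * tuning$steps_per_octave + 1
  key <- floor(kr + 0.5)  # nearest key; half-step ties resolve upward
  if (any(key < 1 | key > tuning$n_keys)) {
    warning("frequencies outside the keyboard range were clamped")
  }
  as.integer(pmin(pmax(key, 1), tuning$n_keys))
}

# Frequency matrix for every (probe, sample) cell, each sample scaled by the
# maximum of its own analysed probe sets.
frequency_matrix <- function(matrix, tuning = sonifex::tuning()) {
  stopifnot(is.matrix(matrix))
  out <- matrix
  for (s in seq_len(ncol(matrix))) {
    sc <- sample_scaling(colnames(matrix)[s], max(matrix[, s]))
    out[, s] <- key_to_frequency(compute_key(matrix[, s], sc, tuning), tuning)
  }
  out
}
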