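#' Metric rhythm specification
#'
#' The metric system divides a semibreve (whole note) into power-of-two
#' subdivisions down to a chosen minimal length, and allows each principal
#' length to carry one or two dots (lengthening it by 50% or 75%). With the
#' default minimal length of 1/8 the principal lengths are
#' {1/8, 1/4, 1/2, 1} — four of them, which enters the default tone-count
#' rule.
#'
#' @param min_length Minimal principal note length as a fraction of a whole
#'   note; one of 1, 1/2, ..., 1/64, or a string like `"1/8"`.
#' @return An object of class `"rhythm_spec"` with fields `min_length`,
#'   `principal_lengths` and `max_dots`.
#' @export
rhythm_spec <- function(min_length = 1 / 8) {
  min_length <- parse_fraction(min_length)
  allowed <- 1 / 2^(0:6)
  if (!any(abs(min_length - allowed) < 1e-12)) {
    stop("min_length must be a power-of-two fraction between 1 and 1/64")
  }
  n <- round(log2(1 / min_length)) + 1L
  structure(list(min_length = min_length,
                 principal_lengths = min_length * 2^(seq_len(n) - 1L),
                 max_dots = 2L),
            class = "rhythm_spec")
}

parse_fraction <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
    x <- if (length(parts) == 2L) {
      as.numeric(parts[1L]) / as.numeric(parts[2L])
    } else {
      as.numeric(parts)
    }
  }
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x > 0)
  x
}

# "3/16"-style exact fraction strings for serialized note tables. Durations
# are principal * (1 | 1.5 | 1.75) with power-of-two principals, so a
# denominator of 4 * 64 always suffices.
fraction_string <- function(x) {
  den <- 256L
  num <- round(x * den)
  vapply(num, function(n) {
    g <- gcd(n, den)
    if (den %/% g == 1L) sprintf("%d", n %/% g)
    else sprintf("%d/%d", n %/% g, den %/% g)
  }, character(1L))
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Variance of calculated frequencies for one probe
#'
#' Sample variance (divisor n - 1) of a probe's per-sample frequencies; the
#' median pseudo-sample is never included. This is the probe's "information
#' content" that drives both variance filtering and tone duration.
#'
#' @param freqs Numeric vector of frequencies (Hz), one per real sample.
#' @return The sample variance.
#' @export
variance_of_frequencies <- function(freqs) {
  stopifnot(is.numeric(freqs))
  if (length(freqs) < 2L) stop("variance needs at least 2 samples")
  stats::var(freqs)
}

#' Quantize variance to a metric note duration
#'
#' Each probe's frequency variance `s2` is mapped to a principal note length
#' and dot count relative to the variance range of the selected probes:
#' `val = ceiling(s2 / ((s2_max - s2_min) * min_length))` is snapped up to
#' the next power of two (`unit`), capped at `1 / min_length`, giving
#' `principal = unit * min_length`; for dots,
#' `da = ceiling(s2 / ((s2_max / 3) * min_length))` and `dots = da mod 3`.
#' The total duration is `principal * (1, 1.5, 1.75)` for 0, 1 or 2 dots.
#' Higher variance therefore never yields a shorter principal length.
#'
#' If `s2_max <= s2_min` (all selected probes equally variable) every probe
#' degenerates to the minimal length with a warning.
#'
#' @param s2 Numeric vector of per-probe frequency variances in
#'   `[0, s2_max]`.
#' @param s2_min,s2_max Minimal and maximal variance among the top
#'   `N + 1` variance-ranked probes (`s2_min` is the variance of the
#'   `(N+1)`-th, so every selected probe exceeds it).
#' @param spec A [rhythm_spec()].
#' @return A data.frame with columns `principal`, `dots`, `fraction` (total
#'   duration as a fraction of a whole note).
#' @export
duration_from_variance <- function(s2, s2_min, s2_max,
                                   spec = rhythm_spec()) {
  stopifnot(inherits(spec, "rhythm_spec"), is.numeric(s2),
            length(s2_min) == 1L, length(s2_max) == 1L)
  ml <- spec$min_length
  if (s2_max <= s2_min) {
    warning("degenerate variance range (s2_max <= s2_min): ",
            "all durations set to the minimal length")
    return(data.frame(principal = rep(ml, length(s2)),
                      dots = rep(0L, length(s2)),
                      fraction = rep(ml, length(s2))))
  }
  if (any(s2 < 0 | s2 > s2_max)) stop("s2 must lie in [0, s2_max]")
  val <- pmax(1, ceiling(s2 / ((s2_max - s2_min) * ml)))
  unit <- 2^ceiling(log2(val))
  unit <- pmin(unit, 1 / ml)
  principal <- unit * ml
  da <- ceiling(s2 / ((s2_max / 3) * ml))
  dots <- as.integer(da %% 3)
  fraction <- principal * (1 + 0.5 * (dots >= 1) + 0.25 * (dots == 2))
  data.frame(principal = principal, dots = dots, fraction = fraction)
}
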