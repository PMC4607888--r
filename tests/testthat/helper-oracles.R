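# Independent oracles and fixture builders shared across test files.

# Toy log2 matrix with named probes/samples.
toy_matrix <- function(values, probes = NULL, samples = NULL) {
  m <- matrix(values, nrow = length(values) / length(samples),
              byrow = TRUE)
  dimnames(m) <- list(probes, samples)
  m
}

# Linear-interpolation percentile between order statistics, written from
# the definition (independent of stats::quantile).
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force duration quantization following the pinned formulas step by
# step, one scalar at a time, with the power-of-two snap done by search.
oracle_duration <- function(s2, s2_min, s2_max, min_length) {
  val <- ceiling(s2 / ((s2_max - s2_min) * min_length))
  if (val < 1) val <- 1
  unit <- 1
  while (unit < val) unit <- unit * 2
  if (unit > 1 / min_length) unit <- 1 / min_length
  principal <- unit * min_length
  da <- ceiling(s2 / ((s2_max / 3) * min_length))
  dots <- da %% 3
  total <- principal * switch(dots + 1, 1, 1.5, 1.75)
  list(principal = principal, dots = dots, fraction = total)
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# Nearest key by log-frequency distance, brute force over all keys.
oracle_nearest_key <- function(f, tn) {
  fk <- tn$f_min * 2^((seq_len(tn$n_keys) - 1) / tn$steps_per_octave)
  which.min(abs(log(f) - log(fk)))
}

# Write a tiny expression TSV and return the path.
write_toy_tsv <- function(m, path = tempfile(fileext = ".tsv")) {
  write_expression_matrix(m, path)
  path
}

# A reproducible small matrix with smooth structure (no planted effects).
random_matrix <- function(n_probes, n_samples, seed = 42) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_probes * n_samples, 7, 2)), n_probes, n_samples)
  dimnames(m) <- list(sprintf("p%03d", seq_len(n_probes)),
                      sprintf("s%d", seq_len(n_samples)))
  m
}
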