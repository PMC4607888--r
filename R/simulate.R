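#' Simulation specification for synthetic expression matrices
#'
#' Describes a log2-intensity matrix with the statistical structure the
#' sonification pipeline assumes: a shared per-probe baseline, independent
#' normal noise on the log2 scale, a handful of sample-specific marker
#' probes per sample, and one designated outlier sample that carries three
#' times as many markers, half up- and half down-regulated (so its melody
#' diverges from the median in both directions, like a mislabelled sample
#' of a different tumour entity).
#'
#' Up-markers are planted on probes from the lower half of the baseline
#' intensity distribution (a sample-specific transcript is silent in the
#' other samples), and the outlier's down-markers on probes from the upper
#' half (a constitutive transcript silenced only in the outlier, as
#' lineage markers are in a divergent cell line). The top of the intensity
#' range thus stays occupied by shared high-expressors, so the per-sample
#' maximum (the key-scaling anchor) is stable across samples and for the
#' median profile, as in real normalized array data.
#'
#' @param n_probes Number of probe sets; must exceed
#'   `default_tone_count(n_samples) + 1` so the default pipeline can run.
#' @param n_samples Number of samples.
#' @param seed Integer seed; the same spec always yields the same matrix.
#' @param baseline_mean,baseline_sd Mean and sd of the per-probe baseline
#'   log2 intensity.
#' @param n_marker_probes Markers planted per non-outlier sample.
#' @param marker_effect Marker effect size in log2 units.
#' @param outlier_marker_multiplier The outlier gets this multiple of
#'   `n_marker_probes` markers.
#' @param noise_sd Sd of the per-cell normal noise on the log2 scale.
#' @param outlier Sample index of the outlier (default: the last sample).
#' @return An object of class `"sim_spec"`.
#' @export
sim_spec <- function(n_probes = 400L, n_samples = 4L, seed = 1L,
                     baseline_mean = 7, baseline_sd = 2,
                     n_marker_probes = 30L, marker_effect = 4,
                     outlier_marker_multiplier = 3L, noise_sd = 0.3,
                     outlier = n_samples) {
  spec <- list(n_probes = as.integer(n_probes),
               n_samples = as.integer(n_samples),
               seed = as.integer(seed),
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               n_marker_probes = as.integer(n_marker_probes),
               marker_effect = marker_effect,
               outlier_marker_multiplier = as.integer(outlier_marker_multiplier),
               noise_sd = noise_sd,
               outlier = as.integer(outlier))
  stopifnot(spec$n_samples >= 2L, spec$n_marker_probes >= 0L,
            is.finite(spec$marker_effect), spec$noise_sd >= 0,
            spec$baseline_sd >= 0,
            spec$outlier >= 1L, spec$outlier <= spec$n_samples)
  min_probes <- default_tone_count(spec$n_samples) + 1L
  if (spec$n_probes <= min_probes) {
    stop(sprintf("n_probes must exceed default_tone_count(n_samples) + 1 = %d",
                 min_probes))
  }
  n_out <- spec$n_marker_probes * spec$outlier_marker_multiplier
  n_up <- spec$n_marker_probes * (spec$n_samples - 1L) +
    (n_out - n_out %/% 2L)
  if (n_up > spec$n_probes %/% 2L || n_out %/% 2L > spec$n_probes %/% 2L) {
    stop("more planted markers than probes in the baseline half they draw from")
  }
  structure(spec, class = "sim_spec")
}

#' Simulate an expression matrix with planted structure
#'
#' Draws one baseline per probe, adds per-cell noise, then adds the marker
#' effects: each non-outlier sample has `n_marker_probes` up-regulated
#' probes; the outlier sample has `outlier_marker_multiplier` times as
#' many, alternating up and down. Marker probe sets are disjoint. The
#' truth record lists every planted effect.
#'
#' @param spec A [sim_spec()].
#' @return List with `matrix` (probes x samples, log2 scale) and `truth`
#'   (list with `outlier_id` and a `markers` data.frame of `probe_id`,
#'   `sample_id`, `effect`).
#' @export
simulate_matrix <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  probes <- sprintf("probe_%04d", seq_len(spec$n_probes))
  samples <- sprintf("sample_%d", seq_len(spec$n_samples))
  outlier_id <- samples[spec$outlier]

  baseline <- stats::rnorm(spec$n_probes, spec$baseline_mean,
                           spec$baseline_sd)
  mat <- baseline +
    matrix(stats::rnorm(spec$n_probes * spec$n_samples, 0, spec$noise_sd),
           spec$n_probes, spec$n_samples)
  dimnames(mat) <- list(probes, samples)

  n_out <- spec$n_marker_probes * spec$outlier_marker_multiplier
  n_dn_out <- n_out %/% 2L
  n_up_out <- n_out - n_dn_out
  low <- which(baseline <= stats::median(baseline))
  high <- setdiff(seq_len(spec$n_probes), low)
  n_up_total <- spec$n_marker_probes * (spec$n_samples - 1L) + n_up_out
  up_rows <- if (n_up_total > 0) low[sample.int(length(low), n_up_total)]
             else integer()
  dn_rows <- if (n_dn_out > 0) high[sample.int(length(high), n_dn_out)]
             else integer()
  truth <- data.frame(probe_id = character(), sample_id = character(),
                      effect = numeric())
  idx <- 0L
  for (s in seq_len(spec$n_samples)) {
    n_up_s <- if (s == spec$outlier) n_up_out else spec$n_marker_probes
    rows <- up_rows[idx + seq_len(n_up_s)]
    idx <- idx + n_up_s
    effects <- rep(spec$marker_effect, n_up_s)
    if (s == spec$outlier) {
      rows <- c(rows, dn_rows)
      effects <- c(effects, rep(-spec$marker_effect, n_dn_out))
    }
    if (!length(rows)) next
    mat[rows, s] <- mat[rows, s] + effects
    truth <- rbind(truth, data.frame(probe_id = probes[rows],
                                     sample_id = samples[s],
                                     effect = effects))
  }
  mat <- pmax(mat, 0)  # log2 MAS5-style intensities are non-negative
  list(matrix = validate_expression_matrix(mat),
       truth = list(outlier_id = outlier_id, markers = truth,
                    spec = unclass(spec)))
}
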