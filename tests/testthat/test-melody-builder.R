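test_that("variance filter keeps the top-k probes and the (k+1)-th variance as context", {
  m <- random_matrix(10, 4, seed = 9)
  sub <- variance_filter(m, tuning(), k = 3)
  # independent sort-by-variance oracle
  f <- m
  for (s in colnames(m)) {
    sc <- sample_scaling(s, max(m[, s]))
    f[, s] <- key_to_frequency(compute_key(m[, s], sc, tuning()), tuning())
  }
  v <- apply(f, 1, var)
  expected <- names(sort(v, decreasing = TRUE))[1:3]
  expect_setequal(rownames(sub), expected)
  # original relative order preserved
  expect_identical(rownames(sub),
                   rownames(m)[sort(match(expected, rownames(m)))])
  expect_equal(attr(sub, "s2_min"), sort(v, decreasing = TRUE)[4])
  expect_equal(attr(sub, "s2_max"), max(v))
  expect_true(all(attr(sub, "variances") > attr(sub, "s2_min")))
})

test_that("variance filter edge cases: identity, argmax, fraction, rejection", {
  m <- random_matrix(10, 3, seed = 2)
  expect_identical(rownames(variance_filter(m, k = 10)), rownames(m))
  one <- variance_filter(m, k = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(nrow(variance_filter(m, k = 0.3)), 3L)  # ceiling(0.3 * 10)
  expect_error(variance_filter(m, k = 11), "exceeds")
})

test_that("default tone count is steps x principal lengths x samples", {
  expect_identical(default_tone_count(4), 192L)
  expect_identical(default_tone_count(6), 288L)
  expect_identical(default_tone_count(1), 48L)
  expect_identical(default_tone_count(4, tuning(steps_per_octave = 24,
                                                n_keys = 176)), 384L)
  expect_identical(default_tone_count(4, spec = rhythm_spec("1/16")), 240L)
})

test_that("median sorting is ascending and stable under ties", {
  tn <- tuning()
  asc <- toy_matrix(c(1, 1, 4, 4, 8, 8), probes = c("a", "b", "c"),
                    samples = c("s1", "s2"))
  expect_identical(sort_by_median(asc, tn), 1:3)
  expect_identical(sort_by_median(asc[3:1, ], tn), 3:1)
  tie <- toy_matrix(c(4, 4, 4, 4, 1, 1), probes = c("a", "b", "c"),
                    samples = c("s1", "s2"))
  expect_identical(sort_by_median(tie, tn), c(3L, 1L, 2L))  # a before b
})

test_that("the pipeline equals the composition of its stages on a seeded matrix", {
  m <- random_matrix(200, 4, seed = 77)
  tn <- tuning(); spec <- rhythm_spec()
  k <- 50
  ms <- build_melody_set(m, tn, spec, k = k)

  # compose by hand
  sub <- variance_filter(m, tn, k)
  keys <- sapply(colnames(sub), function(s) {
    compute_key(sub[, s], sample_scaling(s, max(sub[, s])), tn)
  })
  med <- median_profile(sub)
  med_key <- compute_key(med, sample_scaling("median", max(med)), tn)
  freq <- key_to_frequency(cbind(keys, median = med_key), tn)
  dur <- duration_from_variance(attr(sub, "variances"),
                                attr(sub, "s2_min"), attr(sub, "s2_max"),
                                spec)
  ord <- order(freq[, "median"])

  expect_identical(ms$probe_ids, rownames(sub)[ord])
  expect_equal(unname(ms$frequency), unname(freq[ord, ]))
  expect_equal(ms$duration$fraction, dur$fraction[ord])
  expect_equal(ms$duration$dots, dur$dots[ord])
})

test_that("melody set invariants: aligned durations, sorted median, equal wall time", {
  m <- random_matrix(150, 5, seed = 13)
  ms <- build_melody_set(m, k = 60)
  expect_false(is.unsorted(ms$frequency[, "median"]))
  expect_equal(ncol(ms$frequency), 6L)  # 5 samples + median
  # aligned durations mean identical wall time for every channel
  span <- sum(ms$duration$fraction) * ms$seconds_per_whole_note
  for (s in c(ms$sample_ids, "median")) {
    fc <- frequency_course(ms, s)
    expect_equal(fc$time_s[1], 0)
    expect_equal(fc$time_s[nrow(fc)] +
                   ms$duration$fraction[length(ms$probe_ids)] *
                   ms$seconds_per_whole_note, span)
  }
})

test_that("samples identical to the median profile give identical melodies", {
  base <- random_matrix(30, 1, seed = 4)[, 1]
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- sprintf("p%03d", seq_along(base))
  expect_warning(ms <- build_melody_set(m, k = 10), "degenerate")
  expect_equal(ms$frequency[, "s1"], ms$frequency[, "s2"])
  expect_equal(unname(ms$frequency[, "s1"]),
               unname(ms$frequency[, "median"]))
})

test_that("melody length at the k+1 boundary equals k", {
  m <- random_matrix(51, 3, seed = 8)
  ms <- build_melody_set(m, k = 50)
  expect_length(ms$probe_ids, 50)
  expect_error(build_melody_set(m, k = 51), "k \\+ 1")
})

test_that("frequency courses report onsets as cumulative durations", {
  m <- random_matrix(60, 3, seed = 21)
  ms <- build_melody_set(m, k = 3)
  ms$duration$fraction <- c(1 / 4, 1 / 2, 1 / 4)  # toy durations
  fc <- frequency_course(ms, "s1")
  expect_equal(fc$time_s, c(0, 0.25, 0.75))
  expect_error(frequency_course(ms, "nope"), "unknown sample")
})

test_that("divergence against the median matches closed-form OLS", {
  m <- random_matrix(80, 4, seed = 31)
  ms <- build_melody_set(m, k = 20)
  d <- divergence_course(ms, "s2")
  o <- oracle_ols(d$course$time_s, d$course$abs_diff_hz)
  expect_equal(d$slope, o$slope, tolerance = 1e-9)
  expect_equal(d$intercept, o$intercept, tolerance = 1e-9)
  # a sample equal to the median diverges nowhere
  base <- random_matrix(40, 1, seed = 5)[, 1]
  m2 <- cbind(a = base, b = base, c = base)
  rownames(m2) <- sprintf("q%03d", seq_along(base))
  expect_warning(ms2 <- build_melody_set(m2, k = 10), "degenerate")
  d2 <- divergence_course(ms2, "a")
  expect_equal(d2$course$abs_diff_hz, rep(0, 10))
  expect_equal(d2$slope, 0)
})

test_that("high-pitch counting conserves probes and finds a planted octave-up outlier", {
  m <- random_matrix(60, 4, seed = 12)
  ms <- build_melody_set(m, k = 25)
  hp <- count_high_pitch(ms, threshold = 1e6)
  expect_true(all(hp$counts == 0))
  hp2 <- count_high_pitch(ms, threshold = 987)
  expect_equal(sum(hp2$histogram), length(ms$probe_ids))
  expect_equal(as.integer(hp2$histogram[as.character(2)]),
               sum(hp2$counts == 2))

  # construction oracle for relative mode: push 10 notes of one sample
  # exactly one octave up
  ms3 <- ms
  ms3$frequency[1:10, "s1"] <- 2 * ms3$frequency[1:10, "median"]
  ms3$frequency[11:25, "s1"] <- 0.9 * ms3$frequency[11:25, "median"]
  ms3$frequency[, c("s2", "s3", "s4")] <-
    0.9 * ms3$frequency[, "median"]
  rel <- count_high_pitch(ms3, relative = TRUE)
  expect_equal(sum(rel$counts), 10)
  expect_equal(as.integer(rel$histogram["1"]), 10L)
})
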