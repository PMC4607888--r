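test_that("a whole note renders to exactly one second of audio", {
  path <- tempfile(fileext = ".wav")
  render_wav(data.frame(frequency_hz = 440, duration_s = 1),
             spec = audio_spec(), path = path)
  w <- read_wav(path)
  expect_equal(nrow(w$samples), 44100L)
  expect_equal(w$sample_rate, 44100L)
  expect_equal(w$bits, 16L)
})

test_that("rendered length conserves the sum of durations", {
  path <- tempfile(fileext = ".wav")
  notes <- data.frame(frequency_hz = c(440, 550, 660),
                      duration_s = c(0.25, 0.25, 0.5))
  render_wav(notes, spec = audio_spec(), path = path)
  w <- read_wav(path)
  expect_true(abs(nrow(w$samples) - 44100L) <= 3)  # +-1 frame per note
  expect_equal(nrow(w$samples),
               sum(round(notes$duration_s * 44100)))
})

test_that("the rendered spectrum peaks at the note frequency and never clips", {
  path <- tempfile(fileext = ".wav")
  render_wav(data.frame(frequency_hz = 440, duration_s = 1),
             spec = audio_spec(amplitude = 0.8), path = path)
  x <- read_wav(path)$samples[, 1]
  spec <- Mod(stats::fft(x))[1:22050]
  expect_equal(which.max(spec) - 1L, 440L)  # bin k = k Hz for a 1 s window
  expect_lte(max(abs(x)), 0.8 + 1 / 32767)  # within one quantization LSB
})

test_that("rendering is deterministic and rejects degenerate input", {
  p1 <- tempfile(fileext = ".wav"); p2 <- tempfile(fileext = ".wav")
  notes <- data.frame(frequency_hz = c(100, 200), duration_s = c(0.1, 0.1))
  render_wav(notes, spec = audio_spec(), path = p1)
  render_wav(notes, spec = audio_spec(), path = p2)
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p2, raw(), file.size(p2)))
  expect_error(render_wav(data.frame(frequency_hz = numeric(),
                                     duration_s = numeric()),
                          spec = audio_spec(), path = p1), "empty")
  expect_error(render_wav(data.frame(frequency_hz = -1, duration_s = 1),
                          spec = audio_spec(), path = p1), "positive")
})

test_that("stereo left channel bit-equals the mono median render", {
  sim <- simulate_matrix(sim_spec(seed = 3, n_probes = 250,
                                  n_marker_probes = 10L))
  ms <- build_melody_set(sim$matrix, k = 40)
  sp <- audio_spec()
  st_path <- tempfile(fileext = ".wav")
  mono_path <- tempfile(fileext = ".wav")
  render_stereo(ms, ms$sample_ids[1], sp, st_path)
  render_wav(ms, "median", sp, mono_path)
  st <- read_wav(st_path)
  mono <- read_wav(mono_path)
  expect_equal(ncol(st$samples), 2L)
  expect_identical(st$samples[, 1], mono$samples[, 1])
  # aligned durations guarantee equal channel lengths by construction
  smp <- read_wav(st_path)$samples[, 2]
  expect_length(smp, nrow(mono$samples))
})

test_that("a median-clone sample renders identical stereo channels", {
  base <- random_matrix(40, 1, seed = 19)[, 1]
  m <- cbind(x = base, y = base)
  rownames(m) <- sprintf("p%03d", seq_along(base))
  suppressWarnings(ms <- build_melody_set(m, k = 8))
  path <- tempfile(fileext = ".wav")
  render_stereo(ms, "x", audio_spec(), path)
  w <- read_wav(path)
  expect_identical(w$samples[, 1], w$samples[, 2])
})

test_that("score export writes parseable LilyPond with the A440 naming convention", {
  m <- random_matrix(60, 3, seed = 50)
  ms <- build_melody_set(m, k = 10)
  # force a known first note: key 49 whole note
  ms$key[, ] <- 49L
  ms$frequency[, ] <- 440
  ms$duration$principal <- rep(1, 10)
  ms$duration$dots <- rep(0L, 10)
  ms$duration$fraction <- rep(1, 10)
  path <- tempfile(fileext = ".ly")
  export_score(ms, "s1", path)
  txt <- readLines(path)
  body <- txt[grepl("a'1", txt, fixed = TRUE)]
  expect_length(body, 1)
  expect_true(any(grepl("\\\\clef treble", txt)))

  # round-trip: re-parse pitch/duration tokens of a 3-note melody
  ms3 <- build_melody_set(random_matrix(30, 3, seed = 51), k = 3)
  p3 <- tempfile(fileext = ".ly")
  export_score(ms3, "median", p3)
  tokens <- strsplit(trimws(grep("clef|\\{|\\}|version|%",
                                 readLines(p3), invert = TRUE,
                                 value = TRUE)), " ")[[1]]
  expect_length(tokens, 3)
  names12 <- c("c", "cis", "d", "dis", "e", "f", "fis", "g", "gis", "a",
               "ais", "b")
  for (i in seq_along(tokens)) {
    mth <- regmatches(tokens[i],
                      regexec("^([a-z]+)([',]*)([0-9]+)(\\.*)$", tokens[i]))[[1]]
    pc <- match(mth[2], names12) - 1
    oct <- 3 + nchar(gsub("[^']", "", mth[3])) - nchar(gsub("[^,]", "", mth[3]))
    midi <- 12 * (oct + 1) + pc
    expect_equal(midi, round(69 + 12 * log2(ms3$frequency[i, "median"] / 440)))
    dur <- (1 / as.numeric(mth[4])) *
      c(1, 1.5, 1.75)[nchar(mth[5]) + 1]
    expect_equal(dur, ms3$duration$fraction[i])
  }
})

test_that("score export enforces 12-step notation and non-empty melodies", {
  m <- random_matrix(40, 3, seed = 52)
  ms <- build_melody_set(m, tuning(steps_per_octave = 24, n_keys = 176),
                         k = 5)
  expect_error(export_score(ms, "s1", tempfile()), "12 steps")
  ms2 <- build_melody_set(m, k = 5)
  ms2$probe_ids <- character(0)
  expect_error(export_score(ms2, "s1", tempfile()), "empty")
})

test_that("course plots are written for both modes", {
  m <- random_matrix(60, 3, seed = 53)
  ms <- build_melody_set(m, k = 12)
  for (mode in c("frequency", "divergence")) {
    path <- tempfile(fileext = ".png")
    plot_courses(ms, mode = mode, path = path)
    expect_true(file.exists(path))
    expect_gt(file.size(path), 0)
  }
  expect_error(plot_courses(ms, samples = "nope", path = tempfile(fileext = ".png")),
               "unknown sample")
  expect_error(plot_courses(ms, path = tempfile(fileext = ".bmp")),
               "extension")
})
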