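test_that("waveform CSV IO round-trips and rejects malformed time columns", {
  tt <- seq(0, 5, by = 0.01)
  wf <- waveform(tt, sin(2 * pi * tt), subject_id = "a")
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform(wf, path)
  wf2 <- read_waveform(path, subject_id = "a")
  expect_equal(wf2$time_s, wf$time_s, tolerance = 1e-9)
  expect_equal(wf2$signal, wf$signal, tolerance = 1e-9)
  expect_equal(sampling_rate(wf2), 100, tolerance = 1e-6)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_s,signal", empty)
  expect_error(read_waveform(empty), "empty")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,signal", "0.00,1", "0.01,2", "0.01,3", "0.02,4"), dup)
  expect_error(read_waveform(dup), "row 3")

  nonuni <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,signal", "0.00,1", "0.01,2", "0.05,3", "0.06,4"), nonuni)
  expect_error(read_waveform(nonuni), "non-uniform")
})

test_that("beat detector recovers rate and peak-to-peak of an analytic sinusoid", {
  tt <- seq(0, 60, by = 0.01)
  wf <- waveform(tt, sin(2 * pi * 1.2 * tt))
  b <- detect_beats(wf)
  expect_equal(mean(b$bpm), 72, tolerance = 0.5 / 72)
  expect_equal(mean(b$amplitude), 2, tolerance = 0.05 / 2)
  expect_false(any(b$flag_oob))
  expect_true(all(diff(b$time_s) > 0))
  expect_true(all(b$amplitude > 0))
})

test_that("beat detector recovers a programmed piecewise pulse schedule", {
  p <- clean_params()
  p$bpm_video <- 70; p$bpm_listen <- 90; p$bpm_speak <- 90
  wf <- synth_ppg(p, two_segments(60, 60), seed = 1)
  b <- detect_beats(wf)
  seg1 <- b$bpm[b$time_s > 2 & b$time_s < 58]
  seg2 <- b$bpm[b$time_s > 62 & b$time_s < 118]
  expect_equal(mean(seg1), 70, tolerance = 1 / 70)
  expect_equal(mean(seg2), 90, tolerance = 1 / 90)
})

test_that("flat and too-short traces raise informative errors", {
  tt <- seq(0, 30, by = 0.01)
  expect_error(detect_beats(waveform(tt, rep(1, length(tt)))), "flat|no beats")
  expect_error(detect_beats(waveform(seq(0, 1, 0.01), sin(seq(0, 1, 0.01)))),
               "too short")
})

test_that("per-beat amplitudes match a brute-force scan of each known cycle", {
  wf <- synth_ppg(clean_params(), two_segments(60, 60), seed = 3)
  truth <- attr(wf, "beats_truth")
  b <- detect_beats(wf)
  x <- wf$signal; tt <- wf$time_s
  oracle <- vapply(seq_len(nrow(truth) - 1), function(k) {
    i <- which(tt >= truth$time_s[k] & tt < truth$time_s[k + 1])
    pk <- i[which.max(x[i])]
    x[pk] - min(x[pk:max(i)])
  }, numeric(1))
  idx <- findInterval(b$time_s, truth$time_s)
  interior <- idx >= 2 & idx <= length(oracle) - 1
  expect_gt(sum(interior), 100)
  expect_lt(max(abs(b$amplitude[interior] - oracle[idx[interior]])), 1e-9)
})

test_that("artifact handling: identity, excision, and step-gain correction", {
  times <- seq(1, 119, by = 0.8)
  b <- make_beats(times, amplitude = 1)
  expect_identical(apply_artifacts(b, NULL), b)
  none <- tibble::tibble(kind = character(0), start_s = numeric(0),
                         end_s = numeric(0), t0_s = numeric(0))
  expect_identical(apply_artifacts(b, none), b)

  ex <- tibble::tibble(kind = "excise", start_s = 40, end_s = 55, t0_s = NA_real_)
  b2 <- apply_artifacts(b, ex)
  expect_false(any(b2$time_s >= 40 & b2$time_s < 55))
  expect_equal(nrow(b2), nrow(b) - sum(times >= 40 & times < 55))

  # constant amplitude 1 with an injected x2 step: correction restores 1
  bs <- make_beats(times, amplitude = ifelse(times >= 60, 2, 1))
  st <- tibble::tibble(kind = "step", start_s = NA_real_, end_s = NA_real_,
                       t0_s = 60)
  b3 <- apply_artifacts(bs, st)
  expect_equal(mean(b3$amplitude[b3$time_s >= 60]), 1, tolerance = 0.02)
  expect_equal(b3$time_s, bs$time_s)

  early <- tibble::tibble(kind = "step", start_s = NA_real_, end_s = NA_real_,
                          t0_s = 0.5)
  expect_error(apply_artifacts(b, early), "empty")
})

test_that("step correction is near-idempotent on step-free stationary data", {
  set.seed(4)
  times <- seq(1, 119, by = 0.8)
  amp <- exp(rnorm(length(times), 0, 0.05))
  b <- make_beats(times, amplitude = amp)
  st <- tibble::tibble(kind = "step", start_s = NA_real_, end_s = NA_real_,
                       t0_s = 60)
  b2 <- apply_artifacts(b, st)
  pre <- amp[times >= 40 & times < 60]
  se <- sd(pre) / sqrt(length(pre))
  shift <- abs(mean(b2$amplitude[b2$time_s >= 60]) -
                 mean(b$amplitude[b$time_s >= 60]))
  expect_lt(shift, 2 * se * mean(amp) + 2 * se)
})

test_that("interval means are additive over disjoint intervals and reject empties", {
  b <- make_beats(seq(0.5, 99.5, by = 1), amplitude = 2)
  all1 <- interval_means(b, tibble::tibble(start = 0, end = 100))
  expect_equal(all1$n_beats, 100L)
  expect_equal(all1$mean_amplitude, 2)
  two <- interval_means(b, tibble::tibble(start = c(0, 50), end = c(50, 100)))
  expect_equal(two, all1)
  expect_error(interval_means(b, tibble::tibble(start = 200, end = 300)),
               "no beats")
})

test_that("session normalization: constant physiology gives unit ratios", {
  wf <- synth_ppg(clean_params(), two_segments(60, 120), seed = 5)
  b <- detect_beats(wf)
  turns <- tibble::tibble(speaker_id = c("a", "b", "a", "c"),
                          start_s = c(65, 80, 100, 120),
                          end_s = c(75, 95, 112, 135))
  m <- normalize_session(b, two_segments(60, 120), turns, "a")
  expect_equal(m$tbv_conv_video, 1, tolerance = 0.02)
  expect_equal(m$tbv_speak_listen, 1, tolerance = 0.02)
  expect_equal(m$pulse_speak_listen, 1, tolerance = 0.02)
  expect_false(m$speak_listen_missing)

  m_none <- normalize_session(b, two_segments(60, 120), turns, "zzz")
  expect_true(m_none$speak_listen_missing)
  expect_true(is.na(m_none$tbv_speak_listen))
  expect_false(is.na(m_none$tbv_conv_video))
})

test_that("all normalization ratios are invariant to overall cuff gain", {
  p <- clean_params()
  p$amp_listen <- 0.8; p$amp_speak <- 0.7
  p$bpm_listen <- 82; p$bpm_speak <- 88
  turns <- tibble::tibble(speaker_id = c("a", "b", "a", "b"),
                          start_s = c(65, 85, 110, 140),
                          end_s = c(80, 105, 130, 170))
  own <- turns[turns$speaker_id == "a", ]
  wf <- synth_ppg(p, two_segments(60, 120), own, seed = 6)
  for (cc in c(0.05, 3.7, 1000)) {
    wf2 <- waveform(wf$time_s, wf$signal * cc, subject_id = "a")
    m1 <- normalize_session(detect_beats(wf), two_segments(60, 120), turns, "a")
    m2 <- normalize_session(detect_beats(wf2), two_segments(60, 120), turns, "a")
    for (col in c("tbv_conv_video", "tbv_speak_listen", "pulse_speak_listen")) {
      expect_equal(m2[[col]], m1[[col]], tolerance = 1e-9)
    }
  }
})

test_that("speaking-amplitude suppression is recovered through the full chain", {
  p <- clean_params()
  p$rr_jitter_sdlog <- 0.03; p$amp_jitter_sdlog <- 0.05; p$noise_sd <- 0.03
  p$amp_listen <- 1; p$amp_speak <- 0.9
  turns <- tibble::tibble(speaker_id = rep(c("a", "b"), 4),
                          start_s = 65 + 0:7 * 14,
                          end_s = 65 + 0:7 * 14 + 12)
  own <- turns[turns$speaker_id == "a", ]
  wf <- synth_ppg(p, two_segments(60, 120), own, seed = 7)
  m <- normalize_session(detect_beats(wf), two_segments(60, 120), turns, "a")
  expect_equal(m$tbv_speak_listen, 0.9, tolerance = 0.03 / 0.9)
})
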