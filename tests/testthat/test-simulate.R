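test_that("config validation names the offending field", {
  expect_error(sim_config(sampling_rate_hz = 10), "sampling_rate_hz")
  expect_error(sim_config(amp_conv_factor = 0), "amp_conv_factor")
  expect_error(sim_config(amp_conv_factor = -1), "amp_conv_factor")
  expect_error(sim_config(ln_t_r = 1.2), "ln_t_r")
  expect_error(sim_config(video_s = 0), "video_s")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(seed = 1.5), "seed")
})

test_that("identical seed and config give bit-identical session bundles", {
  cfg <- fast_config(seed = 31)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$saliva, s2$saliva)
  expect_identical(s1$components, s2$components)
  expect_identical(s1$subjects, s2$subjects)
  for (tid in names(s1$sessions)) {
    a <- s1$sessions[[tid]]; b <- s2$sessions[[tid]]
    expect_identical(a$utterances, b$utterances)
    for (sid in names(a$waveforms)) {
      expect_identical(a$waveforms[[sid]]$signal, b$waveforms[[sid]]$signal)
    }
  }
  s3 <- simulate_study(fast_config(seed = 32))
  expect_false(identical(s1$saliva, s3$saliva))
})

test_that("zero-reactivity sessions give unit ratios for every subject", {
  cfg <- null_config(n_triads_study1 = 2, n_triads_study2 = 0,
                     aa_missing_triads_study1 = 0,
                     post_missing_subjects_study1 = 0, seed = 33)
  m <- extract_metrics(simulate_study(cfg))
  expect_true(all(abs(m$tbv_speak_listen - 1) < 0.02, na.rm = TRUE))
  expect_true(all(abs(m$tbv_conv_video - 1) < 0.02))
  expect_true(all(abs(m$pulse_speak_listen - 1) < 0.02, na.rm = TRUE))
})

test_that("a programmed conversation amplitude factor is recovered downstream", {
  cfg <- sim_config(n_triads_study1 = 10, n_triads_study2 = 5,
                    amp_conv_factor = 0.77, amp_conv_sdlog = 0,
                    amp_speak_factor = 1, amp_speak_sdlog = 0,
                    amp_speak_factor_study2 = 1, amp_speak_sdlog_study2 = 0,
                    amp_speak_rank_slope = 0,
                    excise_rate = 0, step_rate = 0,
                    aa_missing_triads_study1 = 0,
                    post_missing_subjects_study1 = 0, seed = 34)
  m <- extract_metrics(simulate_study(cfg))
  expect_equal(mean(m$tbv_conv_video), 0.77, tolerance = 0.03 / 0.77)
})

test_that("synthetic pulse traces honor the programmed schedule and artifacts", {
  p <- clean_params(bpm = 72)
  wf <- synth_ppg(p, two_segments(60, 0), seed = 35)
  b <- detect_beats(wf)
  expect_equal(mean(b$bpm), 72, tolerance = 1 / 72)

  # injected step gain x1.5: detected envelope after t0 is 1.5x before
  wf2 <- wf
  t0 <- 30
  wf2$signal[wf2$time_s >= t0] <- wf2$signal[wf2$time_s >= t0] * 1.5
  b2 <- detect_beats(wf2)
  pre <- mean(b2$amplitude[b2$time_s < t0 - 1])
  post <- mean(b2$amplitude[b2$time_s > t0 + 1])
  expect_equal(post / pre, 1.5, tolerance = 0.02)

  bad <- clean_params(); bad$amp_listen <- 0
  expect_error(synth_ppg(bad, two_segments()), "invalid physiology")

  outside <- tibble::tibble(speaker_id = "x", start_s = 10, end_s = 20)
  expect_error(synth_ppg(clean_params(), two_segments(60, 120), outside),
               "outside the conversation")
})

test_that("equal latent scores share the floor evenly; a dominant score wins", {
  set.seed(36)
  shares <- replicate(200, {
    tk <- synth_turns(c(a = 0, b = 0, c = 0), c(0, 600))
    st <- turn_statistics(tk$turns, roster = c("a", "b", "c"))
    st$floor_s / sum(st$floor_s)
  })
  expect_true(all(abs(rowMeans(shares) - 1 / 3) < 0.03))

  set.seed(37)
  wins <- replicate(200, {
    tk <- synth_turns(c(a = 6, b = 0, c = 0), c(0, 600))
    st <- turn_statistics(tk$turns, roster = c("a", "b", "c"))
    which.max(st$floor_s) == 1
  })
  expect_gte(mean(wins), 0.95)

  empty <- synth_turns(c(a = 1, b = 2, c = 3), c(100, 100))
  expect_equal(nrow(empty$utterances), 0)
  expect_equal(nrow(empty$turns), 0)
})

test_that("saliva generator matches programmed correlations, slopes and bounds", {
  cfg <- sim_config()
  set.seed(38)
  ranks <- perm_ranks(167) # ~500 subjects
  sal <- synth_saliva(cfg, ranks)
  expect_true(all(sal$t_prior > 0 & sal$aa_prior > 0 & sal$c_prior > 0))
  expect_true(all(sal$t_prior >= 1 & sal$t_prior <= 600))
  expect_equal(pearson_r(log(sal$t_prior), log(sal$t_post)), 0.69,
               tolerance = 0.08 / 0.69)

  # programmed rank -> lnAA slope recovered by OLS on the generated panel
  ln_aa_mean <- (log(sal$aa_prior) + log(sal$aa_post)) / 2
  slope <- coef(lm(ln_aa_mean ~ ranks$rank))[2]
  expect_equal(unname(slope), 0.29, tolerance = 0.08 / 0.29)

  degen <- sim_config(ln_t_sd = 0, c_sd = 0, ln_aa_sd = 0,
                      ln_t_rank_slope = 0, c_rank_slope = 0,
                      ln_aa_rank_slope = 0)
  sal0 <- synth_saliva(degen, perm_ranks(5), seed = 1)
  expect_true(all(sal0$t_prior == exp(degen$ln_t_mean)))
  expect_true(all(sal0$c_post == degen$c_mean))
  expect_true(all(sal0$aa_prior == exp(degen$ln_aa_mean)))

  badranks <- dplyr::mutate(perm_ranks(2), rank = rank + 0.2)
  expect_error(synth_saliva(cfg, badranks), "ranks")
})

test_that("stress directions hold for nearly all subjects without heterogeneity", {
  cfg <- sim_config(n_triads_study1 = 5, n_triads_study2 = 0,
                    bpm_conv_increment_sd = 0, bpm_speak_sdlog = 0,
                    bpm_speak_rank_slope = 0, amp_conv_sdlog = 0,
                    amp_speak_sdlog = 0, amp_speak_rank_slope = 0,
                    bpm_speak_sdlog_study2 = 0, amp_speak_sdlog_study2 = 0,
                    excise_rate = 0, step_rate = 0,
                    aa_missing_triads_study1 = 0,
                    post_missing_subjects_study1 = 0, seed = 39)
  m <- extract_metrics(simulate_study(cfg))
  ok <- !is.na(m$tbv_speak_listen)
  expect_gte(mean(m$tbv_conv_video < 1), 0.95)
  expect_gte(mean(m$tbv_speak_listen[ok] < 1), 0.95)
  expect_gte(mean(m$pulse_speak_listen[ok] > 1), 0.95)
})

test_that("sessions carry three subjects, a shared origin, and ground truth", {
  sess <- simulate_session(fast_config(), "T99", 2, seed = 40)
  expect_equal(nrow(sess$subjects), 3)
  expect_equal(sess$segments$start_s[1], 0)
  expect_equal(length(sess$waveforms), 3)
  expect_true(all(vapply(sess$waveforms, function(w) w$time_s[1], 1) == 0))
  expect_equal(sort(unique(sess$components$subject_id)),
               sort(sess$subjects$subject_id))
  expect_equal(nrow(sess$saliva), 3)
  expect_named(sess$ground_truth, c("latent", "latent_rank", "subjects",
                                    "turns", "artifacts"))
  expect_error(simulate_session(fast_config(), "T1", 3), "study")
})
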