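# Shared builders for synthetic fixtures. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

# internal interval algebra, used by set-membership checks in tests
iv <- triadstress:::iv
iv_total <- triadstress:::iv_total
iv_union <- triadstress:::iv_union
iv_intersect <- triadstress:::iv_intersect
iv_setdiff <- triadstress:::iv_setdiff
iv_contains <- triadstress:::iv_contains

two_segments <- function(video_s = 60, conversation_s = 120) {
  tibble::tibble(label = c("video", "conversation"),
                 start_s = c(0, video_s),
                 end_s = c(video_s, video_s + conversation_s))
}

# clean constant-state pulse parameters (no jitter, no noise)
clean_params <- function(bpm = 72, amp = 1, fs = 100) {
  list(bpm_video = bpm, bpm_listen = bpm, bpm_speak = bpm,
       amp_video = amp, amp_listen = amp, amp_speak = amp, gain = amp,
       rr_jitter_sdlog = 0, amp_jitter_sdlog = 0, noise_sd = 0,
       drift_amp = 0, fs = fs)
}

# a small, fast session configuration (shorter segments, fewer triads);
# reactivity parameters stay at the package defaults unless overridden
fast_config <- function(...) {
  sim_config(n_triads_study1 = 2, n_triads_study2 = 1,
             video_s = 60, conversation_s = 180,
             aa_missing_triads_study1 = 1, post_missing_subjects_study1 = 0,
             excise_rate = 0, step_rate = 0, ...)
}

# reactivity switched off entirely: downstream ratios should be 1
null_config <- function(...) {
  sim_config(bpm_conv_increment_mean = 0, bpm_conv_increment_sd = 0,
             bpm_speak_factor = 1, bpm_speak_sdlog = 0, bpm_speak_rank_slope = 0,
             bpm_speak_factor_study2 = 1, bpm_speak_sdlog_study2 = 0,
             amp_conv_factor = 1, amp_conv_sdlog = 0,
             amp_speak_factor = 1, amp_speak_sdlog = 0, amp_speak_rank_slope = 0,
             amp_speak_factor_study2 = 1, amp_speak_sdlog_study2 = 0,
             excise_rate = 0, step_rate = 0, ...)
}

# a synthetic beat series built directly (bypassing waveform synthesis)
make_beats <- function(times, amplitude = 1, bpm = NULL) {
  if (is.null(bpm)) bpm <- c(60 / diff(times), NA)[seq_along(times)]
  b <- tibble::tibble(time_s = times,
                      amplitude = rep_len(amplitude, length(times)),
                      bpm = rep_len(bpm, length(times)),
                      flag_oob = FALSE)
  class(b) <- c("beat_series", class(b))
  b
}

# rank table for saliva-only simulations: one random 1-2-3 permutation per triad
perm_ranks <- function(n_triads, studies = rep(1, n_triads)) {
  tibble::tibble(
    subject_id = paste0("s", seq_len(3 * n_triads)),
    triad_id = rep(paste0("t", seq_len(n_triads)), each = 3),
    study = rep(studies, each = 3),
    rank = as.vector(replicate(n_triads, sample(1:3))),
    member = rep(1:3, n_triads))
}
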