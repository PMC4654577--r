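#' Simulation configuration for synthetic triad sessions
#'
#' Bundles every parameter of the synthetic-session generator. The defaults
#' encode the study conditions the pipeline is designed for: 15 triads of
#' three unacquainted men (10 in the non-competitive study 1, 5 in the
#' reward study 2), a 200 s relaxation video followed by a ~600 s free
#' conversation, pulse accelerating from a 77 BPM video mean to ~84 BPM in
#' conversation, peak-to-peak (TBV) amplitude attenuating to ~0.77 of the
#' video level during conversation and to ~0.88 of listening level during
#' speaking turns (more suppression at lower status rank), and a saliva panel
#' whose transformed analytes (lnT, C, lnAA) match the reported means,
#' spreads, prior/post correlations and the positive rank -> lnAA slope.
#' Between-subject heterogeneity SDs are set from the reported proportions of
#' subjects showing each effect direction (e.g. ~73% showing both faster
#' pulse and lower TBV in conversation). See the methods vignette for the
#' derivation of each default.
#'
#' @param n_triads_study1,n_triads_study2 triads per study.
#' @param video_s,conversation_s segment durations in seconds (> 0).
#' @param sampling_rate_hz waveform sampling rate (>= 20 Hz).
#' @param bpm_video_mean,bpm_video_sd between-subject distribution of resting
#'   (video) pulse, BPM.
#' @param bpm_conv_increment_mean,bpm_conv_increment_sd listening-state pulse
#'   increment from video to conversation, BPM.
#' @param bpm_speak_factor,bpm_speak_sdlog,bpm_speak_rank_slope multiplicative
#'   speaking/listening pulse factor: median, between-subject log-SD, and
#'   log-scale slope per status-rank unit (positive: lower-ranked men show a
#'   larger pulse rise while speaking).
#' @param bpm_speak_factor_study2,bpm_speak_sdlog_study2 the same two
#'   parameters for reward-study triads, whose speaking pulse reactivity was
#'   larger and more variable.
#' @param amp_speak_factor_study2,amp_speak_sdlog_study2 study-2 counterparts
#'   of the speaking amplitude attenuation.
#' @param amp_conv_factor,amp_conv_sdlog conversation amplitude attenuation
#'   relative to video (multiplicative, < 1 under stress) and its log-SD.
#' @param amp_speak_factor,amp_speak_sdlog,amp_speak_rank_slope speaking
#'   amplitude attenuation relative to listening; negative rank slope means
#'   more TBV suppression at lower rank.
#' @param gain_sdlog log-SD of the per-subject cuff gain (raw amplitudes are
#'   partly a function of cuff tightness; all analysis is ratio-based).
#' @param rr_jitter_sdlog,amp_jitter_sdlog per-beat log-normal jitter of the
#'   interbeat interval and amplitude.
#' @param noise_sd,drift_amp,drift_freq additive measurement noise SD and
#'   slow baseline-wander amplitude/frequency, relative to the subject gain.
#' @param turn_dur_meanlog,turn_dur_sdlog,turn_min_s log-normal turn duration
#'   parameters and the generator's minimum emitted turn length (s).
#' @param gap_range uniform range of inter-turn silences (s).
#' @param softmax_temp temperature of the softmax mapping latent status
#'   scores to expected floor-time shares.
#' @param judge_noise SD of the noise added to the latent order when
#'   generating each status component ranking.
#' @param ln_t_mean,ln_t_sd,ln_t_r,ln_t_rank_slope,ln_t_study2_shift lnT
#'   generation: mean, SD, prior/post correlation, slope per rank unit, and
#'   study-2 offset. Analogous arguments for cortisol (`c_*`, ug/dL, raw
#'   scale) and lnAA (`ln_aa_*`).
#' @param t_bounds,c_bounds,aa_bounds assay sensitivity bounds used to
#'   truncate back-transformed values (pg/mL, ug/dL, U/mL).
#' @param triad_re_sd SD of an optional triad-level random shift added to all
#'   analytes (default 0: no within-triad hormone covariance).
#' @param aa_missing_triads_study1 number of leading study-1 triads whose AA
#'   assays are missing (the enzyme was added to the panel late).
#' @param post_missing_subjects_study1 number of study-1 subjects lacking the
#'   post saliva sample.
#' @param excise_rate,step_rate per-subject probabilities of an injected
#'   noise-burst (to be excised) and of a step-gain artifact.
#' @param excise_dur_s,step_gain_range artifact shapes.
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_triads_study1 = 10,
                       n_triads_study2 = 5,
                       video_s = 200,
                       conversation_s = 600,
                       sampling_rate_hz = 100,
                       bpm_video_mean = 77,
                       bpm_video_sd = 9,
                       bpm_conv_increment_mean = 4.8,
                       bpm_conv_increment_sd = 6.8,
                       bpm_speak_factor = 1.075,
                       bpm_speak_factor_study2 = 1.12,
                       bpm_speak_sdlog = 0.042,
                       bpm_speak_sdlog_study2 = 0.095,
                       bpm_speak_rank_slope = 0.028,
                       amp_conv_factor = 0.78,
                       amp_conv_sdlog = 0.232,
                       amp_speak_factor = 0.85,
                       amp_speak_factor_study2 = 0.88,
                       amp_speak_sdlog = 0.2,
                       amp_speak_sdlog_study2 = 0.095,
                       amp_speak_rank_slope = -0.065,
                       gain_sdlog = 0.4,
                       rr_jitter_sdlog = 0.03,
                       amp_jitter_sdlog = 0.05,
                       noise_sd = 0.03,
                       drift_amp = 0.05,
                       drift_freq = 0.05,
                       turn_dur_meanlog = log(18),
                       turn_dur_sdlog = 0.5,
                       turn_min_s = 5,
                       gap_range = c(0.5, 4),
                       softmax_temp = 1.5,
                       judge_noise = 1,
                       ln_t_mean = 4.79, ln_t_sd = 0.40, ln_t_r = 0.69,
                       ln_t_rank_slope = 0.08, ln_t_study2_shift = 0.11,
                       c_mean = 0.185, c_sd = 0.08, c_r = 0.77,
                       c_rank_slope = -0.03, c_study2_shift = 0,
                       ln_aa_mean = 4.38, ln_aa_sd = 0.90, ln_aa_r = 0.44,
                       ln_aa_rank_slope = 0.29, ln_aa_study2_shift = -0.63,
                       t_bounds = c(1, 600),
                       c_bounds = c(0.007, 3),
                       aa_bounds = c(1, 2000),
                       triad_re_sd = 0,
                       aa_missing_triads_study1 = 5,
                       post_missing_subjects_study1 = 1,
                       excise_rate = 1 / 45,
                       step_rate = 3 / 45,
                       excise_dur_s = 15,
                       step_gain_range = c(1.3, 2),
                       seed = NULL) {
  cfg <- as.list(environment())
  check <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  check(n_triads_study1 >= 0 && n_triads_study2 >= 0 &&
          n_triads_study1 + n_triads_study2 >= 1,
        "n_triads_study1", "need at least one triad overall")
  check(video_s > 0, "video_s", "must be > 0")
  check(conversation_s >= 0, "conversation_s", "must be >= 0")
  check(sampling_rate_hz >= 20, "sampling_rate_hz", "must be >= 20 Hz")
  check(amp_conv_factor > 0, "amp_conv_factor", "amplitude factors must be > 0")
  check(amp_speak_factor > 0, "amp_speak_factor", "amplitude factors must be > 0")
  check(bpm_video_mean > 0, "bpm_video_mean", "must be > 0")
  check(bpm_speak_factor > 0, "bpm_speak_factor", "must be > 0")
  for (f in c("ln_t_r", "c_r", "ln_aa_r")) {
    check(abs(cfg[[f]]) <= 1, f, "correlations must lie in [-1, 1]")
  }
  check(amp_speak_factor_study2 > 0, "amp_speak_factor_study2",
        "amplitude factors must be > 0")
  check(bpm_speak_factor_study2 > 0, "bpm_speak_factor_study2", "must be > 0")
  for (f in c("bpm_video_sd", "bpm_conv_increment_sd", "bpm_speak_sdlog",
              "bpm_speak_sdlog_study2", "amp_speak_sdlog_study2",
              "amp_conv_sdlog", "amp_speak_sdlog", "gain_sdlog",
              "rr_jitter_sdlog", "amp_jitter_sdlog", "noise_sd",
              "ln_t_sd", "c_sd", "ln_aa_sd", "triad_re_sd", "judge_noise")) {
    check(cfg[[f]] >= 0, f, "must be >= 0")
  }
  check(all(gap_range > 0) && diff(gap_range) >= 0, "gap_range",
        "must be positive and non-decreasing")
  check(excise_rate >= 0 && excise_rate <= 1, "excise_rate", "must be in [0, 1]")
  check(step_rate >= 0 && step_rate <= 1, "step_rate", "must be in [0, 1]")
  check(all(step_gain_range > 0), "step_gain_range", "must be positive")
  check(is.null(seed) || (is.numeric(seed) && seed == round(seed)),
        "seed", "must be an integer or NULL")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic triad session config: %d + %d triads, video %gs + conversation %gs @ %g Hz\n",
    x$n_triads_study1, x$n_triads_study2, x$video_s, x$conversation_s,
    x$sampling_rate_hz))
  invisible(x)
}

softmax <- function(x, temp = 1) {
  e <- exp((x - max(x)) / temp)
  e / sum(e)
}
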