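# Synthetic triad sessions with known ground truth. Every downstream stage
# (beat detection, artifact correction, turn building, rank aggregation,
# multilevel models) has a parameter-recovery test against what these
# functions programmed in.

#' Synthesize a photoplethysmographic pulse waveform
#'
#' Generates a quasi-periodic pulse train whose instantaneous rate and
#' peak-to-trough envelope follow the subject's state: `video` before the
#' conversation, `speak` during the subject's own turns, `listen` otherwise.
#' Each beat is an asymmetric pulse template (fast upstroke, slow decay -
#' a beta-shaped lobe peaking a quarter of the way through the cycle), scaled
#' by the state amplitude with per-beat log-normal jitter, plus slow baseline
#' wander and white measurement noise. Exact pulse morphology is irrelevant
#' to peak-to-peak statistics; what matters is that each cycle has one clean
#' peak and trough.
#'
#' @param params list of subject parameters: `bpm_video`, `bpm_listen`,
#'   `bpm_speak`, `amp_video`, `amp_listen`, `amp_speak` (all > 0), `gain`,
#'   and optionally `rr_jitter_sdlog`, `amp_jitter_sdlog`, `noise_sd`,
#'   `drift_amp`, `drift_freq`, `fs`.
#' @param segments segment map tibble (`label`, `start_s`, `end_s`) with a
#'   `video` segment preceding a `conversation` segment.
#' @param own_turns tibble of the subject's speaking turns (`start_s`,
#'   `end_s`); must lie inside the conversation segment.
#' @param seed optional integer seed.
#' @return A `ppg_waveform` with the programmed beat schedule attached as
#'   attribute `"beats_truth"` (`time_s`, `amplitude`, `bpm`, `state`).
#' @export
synth_ppg <- function(params, segments, own_turns = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  amps <- c(params$amp_video, params$amp_listen, params$amp_speak)
  if (any(!is.finite(amps)) || any(amps <= 0)) {
    stop("invalid physiology: amplitude factors must be > 0", call. = FALSE)
  }
  bpms <- c(params$bpm_video, params$bpm_listen, params$bpm_speak)
  if (any(!is.finite(bpms)) || any(bpms <= 0)) {
    stop("invalid physiology: pulse rates must be > 0", call. = FALSE)
  }
  fs <- params$fs %||% 100
  rrj <- params$rr_jitter_sdlog %||% 0
  ampj <- params$amp_jitter_sdlog %||% 0
  nsd <- params$noise_sd %||% 0
  damp <- params$drift_amp %||% 0
  dfreq <- params$drift_freq %||% 0.05
  gain <- params$gain %||% 1

  conv <- segments[segments$label == "conversation", , drop = FALSE]
  t0 <- min(segments$start_s)
  t_end <- max(segments$end_s)
  if (!is.null(own_turns) && nrow(own_turns) > 0) {
    if (nrow(conv) == 0) stop("turn schedule given but no conversation segment", call. = FALSE)
    inside <- own_turns$start_s >= min(conv$start_s) - 1e-9 &
      own_turns$end_s <= max(conv$end_s) + 1e-9
    if (!all(inside)) {
      stop("turn schedule lies outside the conversation segment", call. = FALSE)
    }
  }
  video_iv <- {
    v <- segments[segments$label == "video", , drop = FALSE]
    iv(v$start_s, v$end_s)
  }
  speak_iv <- if (is.null(own_turns) || nrow(own_turns) == 0) {
    iv_empty()
  } else {
    iv_merge(iv(own_turns$start_s, own_turns$end_s))
  }

  in_iv <- function(set, t) {
    if (nrow(set) == 0) return(FALSE)
    j <- findInterval(t, set$start)
    j > 0 && t < set$end[j]
  }
  state_at <- function(t) {
    if (in_iv(speak_iv, t)) "speak"
    else if (in_iv(video_iv, t)) "video"
    else "listen"
  }

  # beat schedule: instantaneous rate and amplitude follow the state at onset
  n_guard <- ceiling((t_end - t0) * max(bpms) / 60) + 10
  bt <- numeric(n_guard); ba <- numeric(n_guard); bb <- numeric(n_guard)
  bs <- character(n_guard)
  t <- t0
  nb <- 0L
  for (i in seq_len(n_guard)) {
    if (t >= t_end) break
    st <- state_at(t)
    bpm <- switch(st, video = params$bpm_video, listen = params$bpm_listen,
                  speak = params$bpm_speak)
    amp <- switch(st, video = params$amp_video, listen = params$amp_listen,
                  speak = params$amp_speak)
    period <- 60 / bpm * exp(stats::rnorm(1, 0, rrj))
    nb <- nb + 1L
    bt[nb] <- t; ba[nb] <- amp * exp(stats::rnorm(1, 0, ampj))
    bb[nb] <- 60 / period; bs[nb] <- st
    t <- t + period
  }
  bt <- bt[seq_len(nb)]; ba <- ba[seq_len(nb)]
  bb <- bb[seq_len(nb)]; bs <- bs[seq_len(nb)]

  tt <- seq(t0, t_end - 1 / fs, by = 1 / fs)
  k <- findInterval(tt, bt)
  sig <- numeric(length(tt))
  valid <- k >= 1 & k < length(bt)
  phase <- numeric(length(tt))
  phase[valid] <- (tt[valid] - bt[k[valid]]) / (bt[k[valid] + 1] - bt[k[valid]])
  # beta-lobe template, normalized to unit peak at phase 0.25
  w <- function(x) (x^2 * (1 - x)^6) / (0.25^2 * 0.75^6)
  sig[valid] <- ba[k[valid]] * w(phase[valid])
  sig <- sig + damp * gain * sin(2 * pi * dfreq * tt) +
    stats::rnorm(length(tt), 0, nsd * gain)

  out <- waveform(tt, sig, subject_id = params$subject_id %||% NA_character_)
  attr(out, "beats_truth") <- tibble::tibble(time_s = bt, amplitude = ba,
                                             bpm = bb, state = bs)
  out
}

#' Synthesize a conversation's turn schedule and utterance track
#'
#' Speakers for successive turns are drawn with probabilities given by a
#' softmax of the three latent status scores (the floor alternates between
#' speakers), and turn durations are log-normal with a median that grows
#' with the speaker's share — higher-status members take the floor more often
#' and hold it longer — so the expected share of floor time increases
#' monotonically in latent score (equal scores give shares of 1/3). Turns are
#' separated by short silences. Each turn is emitted as one or two utterances
#' separated by a sub-merge-gap pause, so that turn building reconstructs the
#' schedule.
#'
#' @param latent_scores named numeric vector of 3 latent status scores.
#' @param conversation `c(start_s, end_s)` of the conversation segment.
#' @param temp softmax temperature.
#' @param min_share floor applied to the selection shares (renormalized):
#'   even the lowest-status member occasionally takes the floor, keeping
#'   per-speaker turn counts in the observed range.
#' @param dur_share_gain log-scale gain linking a speaker's share to the
#'   median of their turn-duration distribution.
#' @param turn_dur_meanlog,turn_dur_sdlog,turn_min_s turn-duration model (s).
#' @param gap_range uniform range of inter-turn silences (s).
#' @param seed optional integer seed.
#' @return List with `utterances` and `turns` tibbles (`speaker_id`,
#'   `start_s`, `end_s`). A zero-length conversation yields empty tracks.
#' @export
synth_turns <- function(latent_scores, conversation, temp = 1.5,
                        min_share = 0.12, dur_share_gain = 0.5,
                        turn_dur_meanlog = log(18), turn_dur_sdlog = 0.5,
                        turn_min_s = 5, gap_range = c(0.5, 4), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(latent_scores) == 3)
  ids <- names(latent_scores)
  if (is.null(ids)) ids <- paste0("S", 1:3)
  empty <- tibble::tibble(speaker_id = character(0), start_s = numeric(0),
                          end_s = numeric(0))
  dur_total <- conversation[2] - conversation[1]
  if (dur_total <= 0) return(list(utterances = empty, turns = empty))

  shares <- pmax(softmax(latent_scores, temp), min_share)
  shares <- shares / sum(shares)
  names(shares) <- ids
  t <- conversation[1] + stats::runif(1, gap_range[1], gap_range[2])
  sp <- character(0); s0 <- numeric(0); s1 <- numeric(0)
  prev <- NA_character_
  while (TRUE) {
    remaining <- conversation[2] - t
    if (remaining < turn_min_s + 0.5) break
    # alternation: the floor changes hands between turns
    pool <- if (is.na(prev)) ids else setdiff(ids, prev)
    who <- sample(pool, 1, prob = shares[pool])
    dur <- stats::rlnorm(1, turn_dur_meanlog +
                           dur_share_gain * log(3 * shares[who]),
                         turn_dur_sdlog)
    dur <- min(max(dur, turn_min_s), remaining - 0.25)
    sp <- c(sp, who); s0 <- c(s0, t); s1 <- c(s1, t + dur)
    prev <- who
    t <- t + dur + stats::runif(1, gap_range[1], gap_range[2])
  }
  turns <- tibble::tibble(speaker_id = sp, start_s = s0, end_s = s1)

  utt <- purrr::pmap_dfr(turns, function(speaker_id, start_s, end_s) {
    d <- end_s - start_s
    if (d > 9 && stats::runif(1) < 0.6) {
      gap <- stats::runif(1, 0.3, 1.5)
      cut <- stats::runif(1, start_s + 2, end_s - gap - 2)
      tibble::tibble(speaker_id = speaker_id,
                     start_s = c(start_s, cut + gap),
                     end_s = c(cut, end_s))
    } else {
      tibble::tibble(speaker_id = speaker_id, start_s = start_s, end_s = end_s)
    }
  })
  list(utterances = utt, turns = turns)
}

#' Synthesize a saliva panel for ranked subjects
#'
#' Draws prior/post pairs from bivariate normals on the analysis scales (lnT,
#' raw C, lnAA) with configured means, SDs and prior/post correlations. Each
#' analyte mean shifts linearly with status rank (positive lnAA slope: lower
#' status, higher amylase) and by a study-2 offset; back-transformed values
#' are truncated to the assay sensitivity bounds, so they are always
#' positive.
#'
#' @param config a [sim_config()].
#' @param ranks tibble with columns `subject_id`, `triad_id`, `study`,
#'   `rank`; ranks must lie in `{1, 1.5, 2, 2.5, 3}`.
#' @param seed optional integer seed.
#' @return Raw panel tibble suitable for [transform_panel()].
#' @export
synth_saliva <- function(config, ranks, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(ranks$rank %in% c(1, 1.5, 2, 2.5, 3))) {
    stop("ranks must lie in {1, 1.5, 2, 2.5, 3}", call. = FALSE)
  }
  n <- nrow(ranks)
  re <- stats::setNames(
    stats::rnorm(length(unique(ranks$triad_id)), 0, config$triad_re_sd),
    unique(ranks$triad_id))
  draw_pair <- function(mu, sd, r) {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    prior <- mu + sd * z1
    post <- mu + sd * (r * z1 + sqrt(max(0, 1 - r^2)) * z2)
    list(prior = prior, post = post)
  }
  shift <- unname(re[as.character(ranks$triad_id)])
  cr <- ranks$rank - 2
  s2 <- as.numeric(ranks$study == 2)

  lt <- draw_pair(config$ln_t_mean + config$ln_t_rank_slope * cr +
                    config$ln_t_study2_shift * s2 + shift,
                  config$ln_t_sd, config$ln_t_r)
  cc <- draw_pair(config$c_mean + config$c_rank_slope * cr +
                    config$c_study2_shift * s2 + shift * config$c_sd,
                  config$c_sd, config$c_r)
  la <- draw_pair(config$ln_aa_mean + config$ln_aa_rank_slope * cr +
                    config$ln_aa_study2_shift * s2 + shift,
                  config$ln_aa_sd, config$ln_aa_r)
  clip <- function(x, b) pmin(pmax(x, b[1]), b[2])
  tibble::tibble(
    subject_id = ranks$subject_id,
    triad_id = ranks$triad_id,
    study = ranks$study,
    t_prior = clip(exp(lt$prior), config$t_bounds),
    t_post = clip(exp(lt$post), config$t_bounds),
    c_prior = clip(cc$prior, config$c_bounds),
    c_post = clip(cc$post, config$c_bounds),
    aa_prior = clip(exp(la$prior), config$aa_bounds),
    aa_post = clip(exp(la$post), config$aa_bounds)
  )
}

#' Synthesize the seven status-component rankings for one triad
#'
#' Produces the seven component rank vectors (three judges' gestalt ranks,
#' speaking time, topics introduced, turn count, combined peer evaluation).
#' Each component ranks the latent order perturbed by Gaussian noise of SD
#' `judge_noise`; with zero noise every component equals the latent order
#' (including latent ties). When turn statistics from an actual schedule are
#' supplied, the speaking-time and turn-count components rank those measured
#' values instead.
#'
#' @param latent_ranks named numeric vector of 3 latent ranks (ties allowed:
#'   values in `{1, 1.5, 2, 2.5, 3}`).
#' @param judge_noise noise SD on the latent scale.
#' @param turn_stats optional [turn_statistics()] output for the triad.
#' @param seed optional integer seed.
#' @return Long tibble `component`, `subject_id`, `rank`.
#' @export
synth_status_components <- function(latent_ranks, judge_noise = 0.5,
                                    turn_stats = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(latent_ranks) == 3)
  ids <- names(latent_ranks)
  if (is.null(ids)) ids <- paste0("S", 1:3)
  base_score <- -as.numeric(latent_ranks) # higher score = higher status
  # judges and counts resolve to a discrete scale, so perturbed components can
  # tie within a component -- the only route to tied final ranks
  noisy <- function() {
    rank_components(round(base_score + stats::rnorm(3, 0, judge_noise)))
  }
  comp <- list(
    judge_1 = noisy(), judge_2 = noisy(), judge_3 = noisy()
  )
  if (!is.null(turn_stats)) {
    m <- turn_stats[match(ids, turn_stats$speaker_id), ]
    comp$speaking_time <- rank_components(m$floor_s)
    comp$turn_count <- rank_components(m$n_turns)
  } else {
    comp$speaking_time <- noisy()
    comp$turn_count <- noisy()
  }
  comp$topics <- noisy()
  comp$peer_eval <- noisy()
  purrr::imap_dfr(comp, function(r, nm) {
    tibble::tibble(component = nm, subject_id = ids, rank = as.numeric(r))
  })
}

#' Simulate one complete triad session
#'
#' Draws three subjects with latent status scores, their rank-dependent pulse
#' and amplitude reactivity, a turn schedule, per-subject waveforms (with
#' optional injected noise-burst and step-gain artifacts, annotated in the
#' output), a saliva panel, and the seven status components. All tracks share
#' time origin 0; the video occupies `[0, video_s)` and the conversation
#' `[video_s, video_s + conversation_s)`.
#'
#' @param config a [sim_config()].
#' @param triad_id identifier for the triad.
#' @param study study label (1 or 2).
#' @param seed optional integer seed (bit-identical output for equal seeds).
#' @return A list of class `triad_session`: `subjects`, `segments`,
#'   `utterances`, `turns_truth`, `waveforms` (named list), `artifacts`,
#'   `saliva`, `components`, `ground_truth`.
#' @export
simulate_session <- function(config, triad_id = "T01", study = 1, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!study %in% c(1, 2)) stop("invalid `study`: must be 1 or 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  ids <- paste0(triad_id, "_S", 1:3)
  latent <- stats::setNames(stats::rnorm(3), ids)
  latent_rank <- stats::setNames(rank(-latent, ties.method = "average"), ids)

  segments <- tibble::tibble(
    label = c("video", "conversation"),
    start_s = c(0, config$video_s),
    end_s = c(config$video_s, config$video_s + config$conversation_s))

  tk <- synth_turns(latent, c(config$video_s, config$video_s + config$conversation_s),
                    temp = config$softmax_temp,
                    turn_dur_meanlog = config$turn_dur_meanlog,
                    turn_dur_sdlog = config$turn_dur_sdlog,
                    turn_min_s = config$turn_min_s,
                    gap_range = config$gap_range)
  tstats <- turn_statistics(tk$turns, roster = ids)

  # the observable status measure: seven components aggregated with the tie
  # rule; hormone levels and rank-dependent reactivity are conditioned on
  # this measured rank, as the reported associations are
  components <- synth_status_components(latent_rank, config$judge_noise,
                                        turn_stats = tstats)
  wide <- tidyr::pivot_wider(components, names_from = "subject_id",
                             values_from = "rank")
  cmat <- as.matrix(wide[, ids, drop = FALSE])
  agg <- aggregate_ranks(cmat)
  final_rank <- agg$ranks[ids]

  cr <- final_rank - 2
  bpm_sf <- if (study == 2) config$bpm_speak_factor_study2 else config$bpm_speak_factor
  bpm_ssd <- if (study == 2) config$bpm_speak_sdlog_study2 else config$bpm_speak_sdlog
  amp_sf <- if (study == 2) config$amp_speak_factor_study2 else config$amp_speak_factor
  amp_ssd <- if (study == 2) config$amp_speak_sdlog_study2 else config$amp_speak_sdlog
  bpm_video <- pmax(stats::rnorm(3, config$bpm_video_mean, config$bpm_video_sd), 45)
  inc <- stats::rnorm(3, config$bpm_conv_increment_mean, config$bpm_conv_increment_sd)
  bpm_listen <- pmin(pmax(bpm_video + inc, 45), 170)
  speak_fac <- exp(stats::rnorm(3, log(bpm_sf) +
                                  config$bpm_speak_rank_slope * cr,
                                bpm_ssd))
  bpm_speak <- pmin(bpm_listen * speak_fac, 175)
  gain <- exp(stats::rnorm(3, 0, config$gain_sdlog))
  conv_fac <- exp(stats::rnorm(3, log(config$amp_conv_factor), config$amp_conv_sdlog))
  speak_amp_fac <- exp(stats::rnorm(3, log(amp_sf) +
                                      config$amp_speak_rank_slope * cr,
                                    amp_ssd))

  waveforms <- list()
  artifacts <- tibble::tibble(subject_id = character(0), kind = character(0),
                              start_s = numeric(0), end_s = numeric(0),
                              t0_s = numeric(0), gain = numeric(0))
  t_end <- config$video_s + config$conversation_s
  for (i in 1:3) {
    p <- list(subject_id = ids[i],
              bpm_video = bpm_video[i], bpm_listen = bpm_listen[i],
              bpm_speak = bpm_speak[i],
              amp_video = gain[i],
              amp_listen = gain[i] * conv_fac[i],
              amp_speak = gain[i] * conv_fac[i] * speak_amp_fac[i],
              gain = gain[i],
              rr_jitter_sdlog = config$rr_jitter_sdlog,
              amp_jitter_sdlog = config$amp_jitter_sdlog,
              noise_sd = config$noise_sd,
              drift_amp = config$drift_amp, drift_freq = config$drift_freq,
              fs = config$sampling_rate_hz)
    own <- tk$turns[tk$turns$speaker_id == ids[i], , drop = FALSE]
    wf <- synth_ppg(p, segments, own)

    if (stats::runif(1) < config$excise_rate && config$conversation_s > 120) {
      st <- stats::runif(1, config$video_s + 30,
                         t_end - 30 - config$excise_dur_s)
      en <- st + config$excise_dur_s
      burst <- wf$time_s >= st & wf$time_s < en
      wf$signal[burst] <- wf$signal[burst] + stats::rnorm(sum(burst), 0, 3 * gain[i])
      artifacts <- dplyr::bind_rows(artifacts, tibble::tibble(
        subject_id = ids[i], kind = "excise", start_s = st, end_s = en,
        t0_s = NA_real_, gain = NA_real_))
    }
    if (stats::runif(1) < config$step_rate && t_end > 120) {
      ex <- artifacts[artifacts$subject_id == ids[i] & artifacts$kind == "excise", ]
      for (try in 1:10) {
        t0 <- stats::runif(1, 40, t_end - 40)
        clear <- nrow(ex) == 0 ||
          all(t0 < ex$start_s - 25 | t0 > ex$end_s + 25)
        if (clear) break
      }
      gstep <- stats::runif(1, config$step_gain_range[1], config$step_gain_range[2])
      wf$signal[wf$time_s >= t0] <- wf$signal[wf$time_s >= t0] * gstep
      artifacts <- dplyr::bind_rows(artifacts, tibble::tibble(
        subject_id = ids[i], kind = "step", start_s = NA_real_,
        end_s = NA_real_, t0_s = t0, gain = gstep))
    }
    waveforms[[ids[i]]] <- wf
  }

  rank_tbl <- tibble::tibble(subject_id = ids, triad_id = triad_id,
                             study = study, rank = as.numeric(final_rank))
  saliva <- synth_saliva(config, rank_tbl)
  components <- dplyr::mutate(components, triad_id = triad_id, .before = 1)

  subjects <- tibble::tibble(
    subject_id = ids, triad_id = triad_id, study = study, member = 1:3,
    latent = as.numeric(latent), latent_rank = as.numeric(latent_rank),
    final_rank = as.numeric(final_rank), hierarchy_class = agg$hierarchy_class,
    bpm_video = bpm_video, bpm_listen = bpm_listen, bpm_speak = bpm_speak,
    gain = gain, amp_conv_factor = conv_fac, amp_speak_factor = speak_amp_fac,
    bpm_speak_factor = speak_fac)

  out <- list(triad_id = triad_id, study = study, subjects = subjects,
              segments = segments, utterances = tk$utterances,
              turns_truth = tk$turns, waveforms = waveforms,
              artifacts = artifacts, saliva = saliva, components = components,
              ground_truth = list(latent = latent, latent_rank = latent_rank,
                                  subjects = subjects, turns = tk$turns,
                                  artifacts = artifacts))
  class(out) <- "triad_session"
  out
}

#' Simulate a full two-study collection of triad sessions
#'
#' Runs [simulate_session()] for every triad with per-triad seeds derived
#' deterministically from `config$seed`, then applies the panel's structural
#' missingness: AA assays absent for the leading study-1 triads and the post
#' saliva sample absent for the configured number of study-1 subjects.
#'
#' @param config a [sim_config()].
#' @return A list of class `triad_study`: `sessions` (list), `saliva`,
#'   `components`, `subjects` (combined tibbles), and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  studies <- c(rep(1, config$n_triads_study1), rep(2, config$n_triads_study2))
  n <- length(studies)
  ids <- sprintf("T%02d", seq_len(n))
  seeds <- sample.int(2147483646L, n)
  sessions <- purrr::map(seq_len(n), function(i) {
    simulate_session(config, triad_id = ids[i], study = studies[i],
                     seed = seeds[i])
  })
  names(sessions) <- ids
  saliva <- purrr::map_dfr(sessions, "saliva")
  components <- purrr::map_dfr(sessions, "components")
  subjects <- purrr::map_dfr(sessions, "subjects")

  s1 <- ids[studies == 1]
  aa_na <- s1[seq_len(min(config$aa_missing_triads_study1, length(s1)))]
  saliva$aa_prior[saliva$triad_id %in% aa_na] <- NA_real_
  saliva$aa_post[saliva$triad_id %in% aa_na] <- NA_real_
  if (config$post_missing_subjects_study1 > 0 && length(s1) > 0) {
    drop_subj <- paste0(s1[length(s1)], "_S1")
    hit <- saliva$subject_id %in% drop_subj
    saliva$t_post[hit] <- NA_real_
    saliva$c_post[hit] <- NA_real_
    saliva$aa_post[hit] <- NA_real_
  }

  out <- list(sessions = sessions, saliva = saliva, components = components,
              subjects = subjects, config = config)
  class(out) <- "triad_study"
  out
}
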