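#' Construct a photoplethysmographic waveform trace
#'
#' A waveform trace is a tibble with columns `time_s` and `signal` sampled at
#' uniform spacing, carrying the sampling rate and a subject identifier as
#' attributes. The signal is in arbitrary units: raw amplitudes depend on cuff
#' tightness and are only interpretable after within-subject normalization,
#' which is why every downstream statistic is a ratio.
#'
#' @param time_s numeric vector of sample times (seconds), uniformly spaced.
#' @param signal numeric vector of signal values, same length as `time_s`.
#' @param subject_id subject identifier stored as an attribute.
#' @return A tibble of class `ppg_waveform`.
#' @export
waveform <- function(time_s, signal, subject_id = NA_character_) {
  if (length(time_s) != length(signal)) {
    stop("`time_s` and `signal` must have the same length", call. = FALSE)
  }
  if (length(time_s) < 2) stop("a waveform needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(signal))) stop("all samples must be finite", call. = FALSE)
  dt <- diff(time_s)
  bad <- which(dt <= 0)
  if (length(bad) > 0) {
    stop(sprintf("time column not strictly increasing at row %d", bad[1] + 1L),
         call. = FALSE)
  }
  med <- stats::median(dt)
  off <- which(abs(dt - med) > 1e-6 * med + 1e-9)
  if (length(off) > 0) {
    stop(sprintf("non-uniform sampling at row %d (dt = %g, expected %g)",
                 off[1] + 1L, dt[off[1]], med), call. = FALSE)
  }
  out <- tibble::tibble(time_s = as.numeric(time_s), signal = as.numeric(signal))
  attr(out, "sampling_rate_hz") <- 1 / med
  attr(out, "subject_id") <- subject_id
  class(out) <- c("ppg_waveform", class(out))
  out
}

#' Sampling rate of a waveform trace
#' @param trace a `ppg_waveform`.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(trace) {
  fs <- attr(trace, "sampling_rate_hz")
  if (is.null(fs)) fs <- 1 / stats::median(diff(trace$time_s))
  fs
}

#' Read / write a waveform CSV
#'
#' The on-disk format is a two-column CSV `time_s,signal`. Reading validates
#' strict monotonicity and uniform spacing of the time column and reports the
#' first offending row on failure; writing and re-reading round-trips the
#' trace up to float formatting.
#'
#' @param path file path.
#' @param subject_id optional subject identifier to attach.
#' @return `read_waveform()` returns a `ppg_waveform`; `write_waveform()`
#'   returns `path` invisibly.
#' @export
read_waveform <- function(path, subject_id = NA_character_) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                       progress = FALSE)
  if (nrow(x) == 0) stop(sprintf("empty waveform file: %s", path), call. = FALSE)
  if (!all(c("time_s", "signal") %in% names(x))) {
    stop(sprintf("waveform file %s must have columns time_s,signal", path),
         call. = FALSE)
  }
  waveform(x$time_s, x$signal, subject_id = subject_id)
}

#' @rdname read_waveform
#' @param trace a `ppg_waveform`.
#' @export
write_waveform <- function(trace, path) {
  readr::write_csv(tibble::tibble(time_s = trace$time_s, signal = trace$signal),
                   path, progress = FALSE)
  invisible(path)
}

#' Detect pulse beats and per-beat peak-to-peak amplitude
#'
#' Locates pulse peaks as local maxima of the baseline-detrended signal above
#' an adaptive threshold, with a refractory period of `60 / max_bpm` seconds.
#' Each beat's peak-to-peak amplitude is the height of its peak minus the
#' depth of the following trough (the signal minimum before the next peak),
#' the per-beat proxy for thumb blood volume: the waveform narrows as blood
#' leaves the thumb under sympathetic stress. Instantaneous pulse rate is
#' `60 / spacing` between successive peaks, assigned to the earlier beat.
#'
#' @param trace a `ppg_waveform`.
#' @param min_bpm,max_bpm physiological pulse-rate bounds (defaults 40 and 180
#'   cover seated adults). Rates outside the bounds are flagged in `flag_oob`,
#'   never silently dropped.
#' @return A tibble of class `beat_series` with columns `time_s` (peak time),
#'   `amplitude` (peak-to-peak, a.u.), `bpm`, `flag_oob`.
#' @export
detect_beats <- function(trace, min_bpm = 40, max_bpm = 180) {
  stopifnot(min_bpm > 0, max_bpm > min_bpm)
  fs <- sampling_rate(trace)
  x <- trace$signal
  tt <- trace$time_s
  dur <- tt[length(tt)] - tt[1]
  if (dur < 2 * 60 / min_bpm) {
    stop("trace too short: need at least two beat periods at min_bpm", call. = FALSE)
  }

  # light smoothing (50 ms moving average) then rolling-median baseline removal
  k1 <- max(3L, round(0.05 * fs))
  xs <- stats::filter(x, rep(1 / k1, k1), sides = 2)
  xs[is.na(xs)] <- x[is.na(xs)]
  xs <- as.numeric(xs)
  kb <- round(1.5 * 60 / min_bpm * fs)
  kb <- min(kb, length(x) - 2)
  if (kb %% 2 == 0) kb <- kb + 1
  y <- xs - stats::runmed(xs, kb)

  if (stats::sd(y) < 1e-12 * (abs(stats::median(x)) + 1)) {
    stop("no beats detected: signal is flat", call. = FALSE)
  }

  # block-adaptive threshold so that amplitude level shifts (stress reactivity,
  # step artifacts) do not starve or flood the detector
  block <- max(1L, round(10 * fs))
  nb <- ceiling(length(y) / block)
  bid <- rep(seq_len(nb), each = block, length.out = length(y))
  q <- tapply(y, bid, function(v) stats::quantile(v, 0.95, names = FALSE))
  thr <- 0.35 * pmax(q[bid], 1e-12)

  cand <- which(y > thr &
                  c(-Inf, y[-length(y)]) <= y &
                  y > c(y[-1], -Inf))
  if (length(cand) < 2) stop("no beats detected", call. = FALSE)

  # refractory pruning: keep the larger of two candidates closer than 60/max_bpm
  min_gap <- 60 / max_bpm * fs
  keep <- cand[1]
  for (i in cand[-1]) {
    last <- keep[length(keep)]
    if (i - last >= min_gap) {
      keep <- c(keep, i)
    } else if (y[i] > y[last]) {
      keep[length(keep)] <- i
    }
  }
  if (length(keep) < 2) stop("no beats detected", call. = FALSE)

  pt <- tt[keep]
  nb <- length(keep) - 1L
  amp <- numeric(nb)
  for (k in seq_len(nb)) {
    seg <- x[keep[k]:keep[k + 1]]
    amp[k] <- x[keep[k]] - min(seg)
  }
  bpm <- 60 / diff(pt)
  out <- tibble::tibble(
    time_s = pt[seq_len(nb)],
    amplitude = amp,
    bpm = bpm,
    flag_oob = bpm < min_bpm | bpm > max_bpm
  )
  attr(out, "subject_id") <- attr(trace, "subject_id")
  class(out) <- c("beat_series", class(out))
  out
}

#' Apply artifact annotations to a beat series
#'
#' Two annotation kinds are supported, mirroring how severe movement
#' perturbations are handled during scoring. `excise` removes all beats whose
#' peak falls inside the interval from every downstream statistic. `step`
#' corrects an abrupt cuff-gain change at time `t0_s`: all amplitudes at or
#' after the breakpoint are multiplied by the ratio of mean amplitudes in the
#' `window_s` seconds before versus after the break, so the amplitude series
#' is continuous in the mean across the break. Excisions are applied before
#' step windows are formed, and beat times are never modified.
#'
#' @param beats a `beat_series`.
#' @param annotations a data frame with columns `kind` (`"excise"` or
#'   `"step"`), `start_s`, `end_s` (excise) and `t0_s` (step). `NULL` or zero
#'   rows returns the input unchanged.
#' @param window_s half-width of the step-correction windows (seconds).
#' @return The corrected `beat_series`.
#' @export
apply_artifacts <- function(beats, annotations, window_s = 20) {
  if (is.null(annotations) || nrow(annotations) == 0) return(beats)
  stopifnot(all(annotations$kind %in% c("excise", "step")))
  ex <- annotations[annotations$kind == "excise", , drop = FALSE]
  if (nrow(ex) > 0) {
    drop <- iv_contains(iv(ex$start_s, ex$end_s), beats$time_s)
    beats <- beats[!drop, , drop = FALSE]
  }
  st <- annotations[annotations$kind == "step", , drop = FALSE]
  if (nrow(st) > 0) {
    for (t0 in sort(st$t0_s)) {
      pre <- beats$amplitude[beats$time_s >= t0 - window_s & beats$time_s < t0]
      post <- beats$amplitude[beats$time_s >= t0 & beats$time_s < t0 + window_s]
      if (length(pre) == 0 || length(post) == 0) {
        stop(sprintf(
          "cannot correct step at t0 = %g s: empty %g s window on one side",
          t0, window_s), call. = FALSE)
      }
      ratio <- mean(pre) / mean(post)
      beats$amplitude[beats$time_s >= t0] <- beats$amplitude[beats$time_s >= t0] * ratio
    }
  }
  beats
}

#' Mean pulse rate and peak-to-peak amplitude over an interval set
#'
#' Averages over beats whose peak time lies in the union of the half-open
#' intervals; each beat is one observation, so disjoint intervals and their
#' union give identical results.
#'
#' @param beats a `beat_series`.
#' @param intervals data frame with columns `start` and `end` (seconds).
#' @return A one-row tibble: `mean_bpm`, `mean_amplitude`, `n_beats`.
#' @export
interval_means <- function(beats, intervals) {
  inside <- iv_contains(iv(intervals$start, intervals$end), beats$time_s)
  if (!any(inside)) stop("no beats fall inside the interval set", call. = FALSE)
  tibble::tibble(
    mean_bpm = mean(beats$bpm[inside]),
    mean_amplitude = mean(beats$amplitude[inside]),
    n_beats = sum(inside)
  )
}

#' Per-subject session normalization ratios
#'
#' Computes the stress metrics that make arbitrary-unit amplitudes
#' interpretable: the conversation/video peak-to-peak (TBV) ratio, segment
#' mean pulse rates, and the speaking/listening TBV and pulse ratios. Speaking
#' intervals are the subject's own turns; listening intervals are other
#' members' turns minus any overlap with the subject's own; silence (no one
#' holding a turn) enters neither set. A subject with no speaking turns gets
#' `NA` speak/listen ratios with `speak_listen_missing = TRUE`; segment
#' statistics are still produced.
#'
#' @param beats a `beat_series` (artifact-corrected).
#' @param segments data frame with columns `label` (`"video"`,
#'   `"conversation"`), `start_s`, `end_s`.
#' @param turns a turn track (see [build_turns()]).
#' @param subject subject identifier to analyze.
#' @return One-row tibble of interval metrics.
#' @export
normalize_session <- function(beats, segments, turns, subject) {
  seg_iv <- function(lab) {
    s <- segments[segments$label == lab, , drop = FALSE]
    if (nrow(s) == 0) stop(sprintf("segment map lacks a '%s' segment", lab), call. = FALSE)
    iv(s$start_s, s$end_s)
  }
  video <- seg_iv("video")
  conv <- seg_iv("conversation")
  m_video <- interval_means(beats, video)
  m_conv <- interval_means(beats, conv)

  roster <- unique(c(turns$speaker_id, subject))
  sl <- speaking_listening_sets(turns, subject, roster = roster)
  speaking <- iv_intersect(sl$speaking, conv)
  listening <- iv_intersect(sl$listening, conv)

  has_speech <- iv_total(speaking) > 0 && any(iv_contains(speaking, beats$time_s))
  if (has_speech && iv_total(listening) > 0 && any(iv_contains(listening, beats$time_s))) {
    m_sp <- interval_means(beats, speaking)
    m_li <- interval_means(beats, listening)
    missing_sl <- FALSE
  } else {
    m_sp <- tibble::tibble(mean_bpm = NA_real_, mean_amplitude = NA_real_, n_beats = 0L)
    m_li <- m_sp
    missing_sl <- TRUE
  }

  tibble::tibble(
    subject_id = subject,
    bpm_video = m_video$mean_bpm,
    bpm_conversation = m_conv$mean_bpm,
    pp_video = m_video$mean_amplitude,
    pp_conversation = m_conv$mean_amplitude,
    tbv_conv_video = m_conv$mean_amplitude / m_video$mean_amplitude,
    bpm_speaking = m_sp$mean_bpm,
    bpm_listening = m_li$mean_bpm,
    pp_speaking = m_sp$mean_amplitude,
    pp_listening = m_li$mean_amplitude,
    tbv_speak_listen = m_sp$mean_amplitude / m_li$mean_amplitude,
    pulse_speak_listen = m_sp$mean_bpm / m_li$mean_bpm,
    n_speaking_turns = sum(turns$speaker_id == subject),
    speak_listen_missing = missing_sl
  )
}
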