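# End-to-end orchestration: simulate (or read) -> signal -> turns -> status ->
# statistics, with all report tables gathered in one object.

#' Extract per-subject interval metrics for every subject of a study
#'
#' For each subject: detect beats on the waveform, apply that subject's
#' artifact annotations (excisions before step corrections), rebuild turns
#' from the utterance track, and compute the normalization ratios.
#'
#' @param study a `triad_study` (from [simulate_study()] or [read_study()]).
#' @param min_bpm,max_bpm beat-detector bounds.
#' @param min_turn_s,merge_gap_s turn-building parameters.
#' @return Tibble of per-subject [normalize_session()] rows with `triad_id`
#'   and `study` columns.
#' @export
extract_metrics <- function(study, min_bpm = 40, max_bpm = 180,
                            min_turn_s = 4, merge_gap_s = 2) {
  purrr::map_dfr(study$sessions, function(sess) {
    turns <- build_turns(sess$utterances, min_turn_s = min_turn_s,
                         merge_gap_s = merge_gap_s)
    purrr::map_dfr(names(sess$waveforms), function(sid) {
      beats <- detect_beats(sess$waveforms[[sid]], min_bpm = min_bpm,
                            max_bpm = max_bpm)
      ann <- sess$artifacts[sess$artifacts$subject_id == sid, , drop = FALSE]
      beats <- apply_artifacts(beats, ann)
      normalize_session(beats, sess$segments, turns, sid) |>
        dplyr::mutate(triad_id = sess$triad_id, study = sess$study)
    })
  })
}

#' Run the full triad-stress analysis pipeline
#'
#' Orchestrates every stage on synthetic sessions (default) or on files
#' previously written by [write_study()]: signal extraction and
#' normalization, turn statistics, status-rank aggregation with tie tally,
#' saliva transforms, descriptive tests (video-vs-conversation paired t
#' tests, prior/post correlations, direction proportions), the
#' diagonal-covariance multilevel models (three-level analyte models;
#' rank-on-hormone models per study with mean-centered interactions and
#' simple slopes; rank-on-change models), and post-hoc power for the joint F
#' tests of the OLS versions of the rank models. Also returns the per-subject
#' data behind the ratio-by-rank and amylase-by-rank figures.
#'
#' @param config a [sim_config()] (synthetic mode).
#' @param mode `"synthetic"` or `"files"`.
#' @param input_dir directory written by [write_study()] (files mode).
#' @param out_dir optional directory; when given, all report tables are
#'   written as CSVs together with a `run_log.txt` recording the seed and
#'   session parameters.
#' @return A list of class `triad_report`; see Details for the tables.
#' @export
run_pipeline <- function(config = sim_config(), mode = c("synthetic", "files"),
                         input_dir = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  study <- switch(mode,
    synthetic = simulate_study(config),
    files = {
      if (is.null(input_dir)) stop("`input_dir` required in files mode", call. = FALSE)
      read_study(input_dir)
    })
  report <- analyze_study(study)
  report$seed <- if (mode == "synthetic") config$seed else NA
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Analyze a (synthetic or file-based) study bundle
#'
#' @param study a `triad_study`.
#' @return A `triad_report` list of tidy tables.
#' @export
analyze_study <- function(study) {
  metrics <- extract_metrics(study)

  ranks <- aggregate_status(study$components)
  ties <- tally_ties(ranks)

  panel <- transform_panel(study$saliva) |>
    dplyr::left_join(ranks[, c("triad_id", "subject_id", "final_rank")],
                     by = c("triad_id", "subject_id")) |>
    dplyr::left_join(study$subjects[, c("subject_id", "member")],
                     by = "subject_id")

  metrics <- metrics |>
    dplyr::left_join(ranks[, c("triad_id", "subject_id", "final_rank")],
                     by = c("triad_id", "subject_id"))

  descriptives <- tibble::tibble(
    measure = c("bpm_video", "bpm_conversation", "tbv_conv_video",
                "tbv_speak_listen", "pulse_speak_listen"),
    mean = c(mean(metrics$bpm_video), mean(metrics$bpm_conversation),
             mean(metrics$tbv_conv_video),
             mean(metrics$tbv_speak_listen, na.rm = TRUE),
             mean(metrics$pulse_speak_listen, na.rm = TRUE)))

  tests <- dplyr::bind_rows(
    paired_t_one_tailed(metrics$bpm_conversation, metrics$bpm_video,
                        "greater") |>
      dplyr::mutate(test = "bpm conversation > video", .before = 1),
    paired_t_one_tailed(rep(1, nrow(metrics)), metrics$tbv_conv_video,
                        "greater") |>
      dplyr::mutate(test = "tbv conversation < video", .before = 1),
    {
      ok <- !is.na(metrics$tbv_speak_listen)
      paired_t_one_tailed(rep(1, sum(ok)), metrics$tbv_speak_listen[ok],
                          "greater") |>
        dplyr::mutate(test = "tbv speaking < listening", .before = 1)
    },
    {
      ok <- !is.na(metrics$pulse_speak_listen)
      paired_t_one_tailed(metrics$pulse_speak_listen[ok], rep(1, sum(ok)),
                          "greater") |>
        dplyr::mutate(test = "pulse speaking > listening", .before = 1)
    })

  correlations <- tibble::tibble(
    analyte = c("ln_t", "c", "ln_aa"),
    r_prior_post = c(pearson_r(panel$ln_t_prior, panel$ln_t_post),
                     pearson_r(panel$c_prior, panel$c_post),
                     tryCatch(pearson_r(panel$ln_aa_prior, panel$ln_aa_post),
                              error = function(e) NA_real_)))

  proportions <- proportion_summary(metrics)

  long <- panel |>
    tidyr::pivot_longer(
      cols = c("ln_t_prior", "ln_t_post", "c_prior", "c_post",
               "ln_aa_prior", "ln_aa_post"),
      names_to = c("analyte", "time"),
      names_pattern = "(ln_t|c|ln_aa)_(prior|post)",
      values_to = "value") |>
    dplyr::mutate(time_num = as.numeric(.data$time == "post"),
                  competition = as.numeric(.data$study == 2))

  fit_analyte <- function(an) {
    d <- long[long$analyte == an & !is.na(long$value) & !is.na(long$final_rank), ]
    fit_diagonal_mlm(d, value ~ competition * time_num * final_rank,
                     repeated = c("member", "time"), subject = "triad_id")
  }
  analyte_models <- purrr::map(
    stats::setNames(c("ln_t", "c", "ln_aa"), c("ln_t", "c", "ln_aa")),
    function(an) tryCatch(fit_analyte(an), error = function(e) NULL))

  fit_rank <- function(d, f) {
    tryCatch(fit_diagonal_mlm(d, f, repeated = "member", subject = "triad_id"),
             error = function(e) NULL)
  }
  rank_models <- list()
  slopes <- list()
  power_rows <- list()
  for (st in c(1, 2)) {
    d <- panel[panel$study == st & !is.na(panel$final_rank), ]
    d_tc <- d[stats::complete.cases(d[, c("ln_t_mean", "c_mean")]), ]
    d_ta <- d[stats::complete.cases(d[, c("ln_t_mean", "ln_aa_mean")]), ]
    m_tc <- fit_rank(d_tc, final_rank ~ ln_t_mean * c_mean)
    m_ta <- fit_rank(d_ta, final_rank ~ ln_t_mean * ln_aa_mean)
    rank_models[[paste0("study", st, "_t_c")]] <- m_tc
    rank_models[[paste0("study", st, "_t_aa")]] <- m_ta
    if (!is.null(m_tc)) {
      slopes[[paste0("study", st, "_t_by_c")]] <-
        simple_slopes(m_tc, "ln_t_mean", "c_mean")
      r2 <- ols_r2(d_tc, final_rank ~ ln_t_mean * c_mean)
      power_rows[[paste0("study", st, "_t_c")]] <-
        posthoc_power_f(r2, nrow(d_tc), 3) |>
        dplyr::mutate(model = paste0("study", st, "_t_c"), .before = 1)
    }
    if (!is.null(m_ta)) {
      r2 <- ols_r2(d_ta, final_rank ~ ln_t_mean * ln_aa_mean)
      power_rows[[paste0("study", st, "_t_aa")]] <-
        posthoc_power_f(r2, nrow(d_ta), 3) |>
        dplyr::mutate(model = paste0("study", st, "_t_aa"), .before = 1)
    }
    for (ch in c("d_ln_t", "d_c", "d_ln_aa")) {
      dd <- d[!is.na(d[[ch]]), ]
      if (nrow(dd) >= 9) {
        rank_models[[paste0("study", st, "_", ch)]] <-
          fit_rank(dd, stats::as.formula(paste("final_rank ~", ch)))
      }
    }
  }
  power <- dplyr::bind_rows(power_rows)

  fig_ratio_rank <- metrics[, c("subject_id", "triad_id", "study", "final_rank",
                                "tbv_speak_listen", "pulse_speak_listen")]
  fig_amylase_rank <- panel[, c("subject_id", "triad_id", "study",
                                "final_rank", "ln_aa_mean")]

  out <- list(metrics = metrics, ranks = ranks, ties = ties, panel = panel,
              descriptives = descriptives, tests = tests,
              correlations = correlations, proportions = proportions,
              analyte_models = analyte_models, rank_models = rank_models,
              simple_slopes = slopes, power = power,
              fig_ratio_rank = fig_ratio_rank,
              fig_amylase_rank = fig_amylase_rank)
  class(out) <- "triad_report"
  out
}

ols_r2 <- function(d, f) {
  vars <- all.vars(f)
  dd <- d
  for (v in vars) dd[[v]] <- as.numeric(scale(dd[[v]]))
  summary(stats::lm(f, data = dd))$r.squared
}

#' @export
print.triad_report <- function(x, ...) {
  cat("Triad stress pipeline report\n")
  cat(sprintf("  subjects: %d, triads: %d, tied pairs: %d / %d\n",
              nrow(x$metrics), x$ties$n_triads, x$ties$n_ties, x$ties$n_pairs))
  cat("  descriptives:\n")
  print(as.data.frame(x$descriptives), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write all report tables of a pipeline run to CSV
#'
#' @param report a `triad_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, nm) readr::write_csv(x, file.path(out_dir, nm), progress = FALSE)
  wr(report$metrics, "metrics.csv")
  wr(report$ranks, "status_ranks.csv")
  wr(report$descriptives, "descriptives.csv")
  wr(report$tests, "paired_tests.csv")
  wr(report$correlations, "correlations.csv")
  wr(report$proportions, "proportions.csv")
  wr(report$power, "power.csv")
  wr(report$fig_ratio_rank, "fig_ratio_by_rank.csv")
  wr(report$fig_amylase_rank, "fig_amylase_by_rank.csv")
  models <- purrr::imap_dfr(
    c(report$analyte_models, report$rank_models),
    function(m, nm) if (is.null(m)) NULL else dplyr::mutate(tidy(m), model = nm,
                                                            .before = 1))
  wr(models, "model_coefficients.csv")
  log <- c(sprintf("triadstress %s, R %s", as.character(packageVersion("triadstress")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed: %s", report$seed %||% NA),
           sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Write / read a study bundle as plain-text files
#'
#' `write_study()` lays a `triad_study` out as one directory per triad with
#' per-subject waveform CSVs (`time_s,signal`), the utterance track as a
#' tab-delimited label file, segment/artifact/ground-truth YAML, plus
#' top-level `saliva.csv` and `status_components.csv`. `read_study()`
#' reconstructs the bundle.
#'
#' @param study a `triad_study`.
#' @param dir directory.
#' @return `write_study()` returns `dir` invisibly; `read_study()` a
#'   `triad_study`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$saliva, file.path(dir, "saliva.csv"), progress = FALSE)
  readr::write_csv(study$components, file.path(dir, "status_components.csv"),
                   progress = FALSE)
  for (sess in study$sessions) {
    sd <- file.path(dir, "sessions", sess$triad_id)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(sess$waveforms)) {
      write_waveform(sess$waveforms[[sid]],
                     file.path(sd, paste0("waveform_", sid, ".csv")))
    }
    write_utterances(sess$utterances, file.path(sd, "utterances.txt"))
    yaml::write_yaml(list(
      triad_id = sess$triad_id, study = sess$study,
      subjects = as.list(sess$subjects$subject_id),
      segments = lapply(seq_len(nrow(sess$segments)), function(i)
        as.list(sess$segments[i, ])),
      artifacts = if (nrow(sess$artifacts) == 0) list() else
        lapply(seq_len(nrow(sess$artifacts)), function(i)
          as.list(sess$artifacts[i, ])),
      ground_truth = list(
        latent = as.list(sess$ground_truth$latent),
        latent_rank = as.list(sess$ground_truth$latent_rank))
    ), file.path(sd, "session.yml"))
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  saliva <- readr::read_csv(file.path(dir, "saliva.csv"),
                            col_types = readr::cols(
                              subject_id = "c", triad_id = "c",
                              .default = "d"), progress = FALSE)
  components <- readr::read_csv(file.path(dir, "status_components.csv"),
                                col_types = readr::cols(
                                  triad_id = "c", component = "c",
                                  subject_id = "c", rank = "d"),
                                progress = FALSE)
  sdirs <- list.dirs(file.path(dir, "sessions"), recursive = FALSE)
  sessions <- purrr::map(sdirs, function(sd) {
    meta <- yaml::read_yaml(file.path(sd, "session.yml"))
    segs <- dplyr::bind_rows(lapply(meta$segments, tibble::as_tibble))
    arts <- if (length(meta$artifacts) == 0) {
      tibble::tibble(subject_id = character(0), kind = character(0),
                     start_s = numeric(0), end_s = numeric(0),
                     t0_s = numeric(0), gain = numeric(0))
    } else {
      dplyr::bind_rows(lapply(meta$artifacts, function(a)
        tibble::as_tibble(lapply(a, function(v) if (is.null(v)) NA else v))))
    }
    sids <- unlist(meta$subjects)
    wfs <- stats::setNames(lapply(sids, function(sid)
      read_waveform(file.path(sd, paste0("waveform_", sid, ".csv")),
                    subject_id = sid)), sids)
    utt <- read_utterances(file.path(sd, "utterances.txt"))
    lr <- unlist(meta$ground_truth$latent_rank)
    sess <- list(triad_id = meta$triad_id, study = meta$study,
                 subjects = tibble::tibble(subject_id = sids,
                                           triad_id = meta$triad_id,
                                           study = meta$study, member = seq_along(sids)),
                 segments = segs, utterances = utt, waveforms = wfs,
                 artifacts = arts,
                 ground_truth = list(latent = unlist(meta$ground_truth$latent),
                                     latent_rank = lr))
    class(sess) <- "triad_session"
    sess
  })
  names(sessions) <- purrr::map_chr(sessions, "triad_id")
  out <- list(sessions = sessions, saliva = saliva, components = components,
              subjects = purrr::map_dfr(sessions, "subjects"),
              config = NULL)
  class(out) <- "triad_study"
  out
}

#' Validate study input files
#'
#' Schema and invariant checks over a directory written in the
#' [write_study()] layout: waveform monotonicity/uniformity and negative
#' timestamps, utterance interval sanity, saliva positivity and
#' missing-assay patterns (missing AA assays produce a warning-level finding,
#' not an error, since the enzyme entered the panel late).
#'
#' @param dir input directory.
#' @return Tibble of findings: `file`, `severity` (`"error"`/`"warning"`),
#'   `message`, `row` (first offending row or `NA`). Zero rows means all
#'   checks passed.
#' @export
validate_inputs <- function(dir) {
  findings <- list()
  add <- function(file, severity, message, row = NA_integer_) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      file = file, severity = severity, message = message, row = as.integer(row))
  }
  sal_path <- file.path(dir, "saliva.csv")
  if (!file.exists(sal_path)) {
    add("saliva.csv", "error", "missing file")
  } else {
    sal <- readr::read_csv(sal_path, col_types = readr::cols(
      subject_id = "c", triad_id = "c", .default = "d"), progress = FALSE)
    for (col in c("t_prior", "t_post", "c_prior", "c_post", "aa_prior", "aa_post")) {
      bad <- which(!is.na(sal[[col]]) & sal[[col]] <= 0)
      if (length(bad) > 0) {
        add("saliva.csv", "error",
            sprintf("nonpositive %s value", col), bad[1])
      }
    }
    aa_na_triads <- unique(sal$triad_id[is.na(sal$aa_prior)])
    if (length(aa_na_triads) > 0) {
      add("saliva.csv", "warning",
          sprintf("AA assays missing for %d triad(s)", length(aa_na_triads)))
    }
  }
  sdirs <- list.dirs(file.path(dir, "sessions"), recursive = FALSE)
  for (sd in sdirs) {
    for (wf in list.files(sd, pattern = "^waveform_.*\\.csv$", full.names = TRUE)) {
      x <- tryCatch(readr::read_csv(wf, col_types = "dd", progress = FALSE),
                    error = function(e) NULL)
      fname <- file.path(basename(sd), basename(wf))
      if (is.null(x) || nrow(x) == 0) { add(fname, "error", "empty or unreadable"); next }
      neg <- which(x$time_s < 0)
      if (length(neg) > 0) add(fname, "error", "negative timestamp", neg[1])
      dt <- diff(x$time_s)
      nm <- which(dt <= 0)
      if (length(nm) > 0) add(fname, "error", "non-monotone time column", nm[1] + 1)
    }
    up <- file.path(sd, "utterances.txt")
    if (file.exists(up)) {
      u <- read_utterances(up)
      bad <- which(u$end_s <= u$start_s)
      if (length(bad) > 0) {
        add(file.path(basename(sd), "utterances.txt"), "error",
            "utterance with end <= start", bad[1])
      }
    }
  }
  if (length(findings) == 0) {
    tibble::tibble(file = character(0), severity = character(0),
                   message = character(0), row = integer(0))
  } else {
    dplyr::bind_rows(findings)
  }
}
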