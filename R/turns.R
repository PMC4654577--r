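#' Read / write an utterance track (Audacity label format)
#'
#' Utterance tracks are tab-delimited label files with three columns
#' `start_s<TAB>end_s<TAB>speaker_id` and no header.
#'
#' @param path file path.
#' @return `read_utterances()` returns a tibble with columns `speaker_id`,
#'   `start_s`, `end_s`.
#' @export
read_utterances <- function(path) {
  x <- readr::read_tsv(path, col_names = c("start_s", "end_s", "speaker_id"),
                       col_types = "ddc", progress = FALSE)
  tibble::tibble(speaker_id = x$speaker_id, start_s = x$start_s, end_s = x$end_s)
}

#' @rdname read_utterances
#' @param utterances tibble with columns `speaker_id`, `start_s`, `end_s`.
#' @export
write_utterances <- function(utterances, path) {
  readr::write_tsv(utterances[, c("start_s", "end_s", "speaker_id")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Build speaking turns from an utterance track
#'
#' A speaking turn is a fairly consistent utterance by one person lasting more
#' than `min_turn_s` seconds, allowing short pauses or interjections by
#' others. Same-speaker utterances separated by gaps of at most `merge_gap_s`
#' are merged into one span (interjections by other speakers during the gap do
#' not block the merge); merged spans strictly longer than `min_turn_s` become
#' turns, shorter spans are discarded.
#'
#' @param utterances tibble with columns `speaker_id`, `start_s`, `end_s`.
#' @param min_turn_s minimum turn duration in seconds (strictly greater-than).
#' @param merge_gap_s maximum same-speaker gap bridged when merging.
#' @return A turn track: tibble `speaker_id`, `start_s`, `end_s` sorted by
#'   start time, with per-speaker turns non-overlapping.
#' @export
build_turns <- function(utterances, min_turn_s = 4, merge_gap_s = 2) {
  if (is.null(utterances) || nrow(utterances) == 0) {
    return(tibble::tibble(speaker_id = character(0), start_s = numeric(0),
                          end_s = numeric(0)))
  }
  stopifnot(all(utterances$end_s > utterances$start_s))
  out <- utterances |>
    dplyr::group_by(.data$speaker_id) |>
    dplyr::arrange(.data$start_s, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      spans <- iv(d$start_s[1], d$end_s[1])
      if (nrow(d) > 1) {
        for (i in 2:nrow(d)) {
          last <- nrow(spans)
          if (d$start_s[i] - spans$end[last] <= merge_gap_s) {
            spans$end[last] <- max(spans$end[last], d$end_s[i])
          } else {
            spans <- rbind(spans, iv(d$start_s[i], d$end_s[i]))
          }
        }
      }
      spans[spans$end - spans$start > min_turn_s, , drop = FALSE]
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(start_s = "start", end_s = "end") |>
    dplyr::arrange(.data$start_s)
  out[, c("speaker_id", "start_s", "end_s")]
}

#' Speaking and listening interval sets for one subject
#'
#' Speaking intervals are the subject's own turns. Listening intervals are the
#' union of the other speakers' turns minus any overlap with the subject's own
#' turns: overlapping speech is attributed to the subject's own speaking,
#' since stress attribution follows own vocal effort. Silence, when no one
#' holds a turn, belongs to neither set; set `include_silence = TRUE` to count
#' silence within `extent` as listening instead.
#'
#' @param turns a turn track.
#' @param subject subject identifier; must be in `roster`.
#' @param roster triad roster; defaults to the speakers present in `turns`.
#' @param include_silence logical; see above.
#' @param extent optional `c(start, end)` conversation extent, required when
#'   `include_silence = TRUE`.
#' @return List with elements `speaking` and `listening`, each a tibble of
#'   disjoint half-open intervals (`start`, `end`).
#' @export
speaking_listening_sets <- function(turns, subject,
                                    roster = unique(turns$speaker_id),
                                    include_silence = FALSE, extent = NULL) {
  if (!subject %in% roster) {
    stop(sprintf("unknown subject '%s': not in roster", subject), call. = FALSE)
  }
  own <- turns[turns$speaker_id == subject, , drop = FALSE]
  oth <- turns[turns$speaker_id != subject, , drop = FALSE]
  speaking <- iv_merge(iv(own$start_s, own$end_s))
  if (include_silence) {
    if (is.null(extent)) stop("`extent` required when include_silence = TRUE", call. = FALSE)
    listening <- iv_setdiff(iv(extent[1], extent[2]), speaking)
  } else {
    listening <- iv_setdiff(iv_merge(iv(oth$start_s, oth$end_s)), speaking)
  }
  list(speaking = speaking, listening = listening)
}

#' Per-speaker turn statistics
#'
#' Counts and floor time per speaker; topic counts are annotation inputs (not
#' computed from audio) and are passed through when supplied.
#'
#' @param turns a turn track.
#' @param roster speakers to report (zeros for speakers with no turns).
#' @param topics optional tibble `speaker_id`, `n_topics` to join.
#' @return Tibble `speaker_id`, `n_turns`, `floor_s` (and `n_topics` if given).
#' @export
turn_statistics <- function(turns, roster = unique(turns$speaker_id), topics = NULL) {
  base <- tibble::tibble(speaker_id = as.character(roster))
  stats <- turns |>
    dplyr::group_by(.data$speaker_id) |>
    dplyr::summarise(n_turns = dplyr::n(),
                     floor_s = sum(.data$end_s - .data$start_s),
                     .groups = "drop")
  out <- base |>
    dplyr::left_join(stats, by = "speaker_id") |>
    dplyr::mutate(n_turns = dplyr::coalesce(.data$n_turns, 0L),
                  floor_s = dplyr::coalesce(.data$floor_s, 0))
  if (!is.null(topics)) out <- dplyr::left_join(out, topics, by = "speaker_id")
  out
}
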