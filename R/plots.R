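# ggplot2 views of the main result types.

#' Plot a waveform trace with optional detected beats
#'
#' @param trace a `ppg_waveform`.
#' @param beats optional `beat_series` to overlay as peak markers.
#' @param window optional `c(start, end)` time window (s).
#' @return A ggplot object.
#' @export
plot_waveform <- function(trace, beats = NULL, window = NULL) {
  d <- tibble::tibble(time_s = trace$time_s, signal = trace$signal)
  if (!is.null(window)) d <- d[d$time_s >= window[1] & d$time_s < window[2], ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)")
  if (!is.null(beats)) {
    b <- beats
    if (!is.null(window)) b <- b[b$time_s >= window[1] & b$time_s < window[2], ]
    p <- p + ggplot2::geom_vline(xintercept = b$time_s, colour = "firebrick",
                                 alpha = 0.3, linewidth = 0.2)
  }
  p
}

#' Speaking/listening ratios against status rank
#'
#' Scatter of each subject's speaking/listening TBV and pulse ratios against
#' final status rank, with least-squares trend lines: under the stress-based
#' account of status allocation the TBV ratio slopes down and the pulse
#' ratio up as rank descends.
#'
#' @param fig_data tibble with `final_rank`, `tbv_speak_listen`,
#'   `pulse_speak_listen` (e.g. `report$fig_ratio_rank`).
#' @return A ggplot object.
#' @export
plot_speak_listen <- function(fig_data) {
  d <- fig_data |>
    tidyr::pivot_longer(cols = c("tbv_speak_listen", "pulse_speak_listen"),
                        names_to = "measure", values_to = "ratio") |>
    dplyr::filter(!is.na(.data$ratio), !is.na(.data$final_rank))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$final_rank, y = .data$ratio,
                                  colour = .data$measure)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "status rank (1 = high, 3 = low)",
                  y = "speaking / listening ratio")
}

#' Mean lnAA against status rank, by study
#'
#' @param fig_data tibble with `final_rank`, `ln_aa_mean`, `study`
#'   (e.g. `report$fig_amylase_rank`).
#' @return A ggplot object.
#' @export
plot_amylase_rank <- function(fig_data) {
  d <- dplyr::filter(fig_data, !is.na(.data$ln_aa_mean), !is.na(.data$final_rank))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$final_rank, y = .data$ln_aa_mean)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~study, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "status rank (1 = high, 3 = low)", y = "mean lnAA")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Power curve for a joint F test
#'
#' Plots power against total sample size at the result's effect size.
#'
#' @param object a `power_result`.
#' @param n_range sample sizes to sweep.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.power_result <- function(object, n_range = NULL, ...) {
  if (is.null(n_range)) {
    n_range <- seq(object$df1 + 2, max(4 * (object$df1 + object$df2 + 1), 60))
  }
  d <- purrr::map_dfr(n_range, function(n)
    posthoc_power_f(object$r2, n, object$df1, object$alpha))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$df1 + .data$df2 + 1, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(data = object,
                        colour = "firebrick") +
    ggplot2::labs(x = "total N", y = "power",
                  title = sprintf("Joint F test power, f² = %.3f", object$f2))
}
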