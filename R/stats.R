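#' Transform a raw saliva panel to analysis scales
#'
#' Testosterone (pg/mL) and alpha-amylase (U/mL) are positively skewed and are
#' log-transformed to `ln_t` and `ln_aa`; cortisol (ug/dL) is left on its raw
#' scale. Prior-to-post changes (`d_*`, post minus prior) and session mean
#' levels (`*_mean`) are computed on the analysis scales. A subject missing
#' the post sample keeps the prior value as the mean level, flagged in
#' `post_missing`.
#'
#' @param raw tibble with columns `subject_id`, `triad_id`, `study`,
#'   `t_prior`, `t_post`, `c_prior`, `c_post`, `aa_prior`, `aa_post` (`NA`
#'   allowed for missing samples/assays).
#' @return The panel with `ln_t_*`, `c_*`, `ln_aa_*`, `d_*`, `*_mean` and
#'   `post_missing` columns added.
#' @export
transform_panel <- function(raw) {
  need <- c("subject_id", "triad_id", "study",
            "t_prior", "t_post", "c_prior", "c_post", "aa_prior", "aa_post")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop(sprintf("panel lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  analyte_cols <- c("t_prior", "t_post", "c_prior", "c_post", "aa_prior", "aa_post")
  bad <- vapply(seq_len(nrow(raw)), function(i) {
    v <- unlist(raw[i, analyte_cols])
    any(!is.na(v) & v <= 0)
  }, logical(1))
  if (any(bad)) {
    stop(sprintf("nonpositive analyte value(s) for subject(s): %s",
                 paste(raw$subject_id[bad], collapse = ", ")), call. = FALSE)
  }
  mean2 <- function(a, b) ifelse(is.na(b), a, ifelse(is.na(a), b, (a + b) / 2))
  raw |>
    dplyr::mutate(
      ln_t_prior = log(.data$t_prior),
      ln_t_post = log(.data$t_post),
      ln_aa_prior = log(.data$aa_prior),
      ln_aa_post = log(.data$aa_post),
      d_ln_t = .data$ln_t_post - .data$ln_t_prior,
      d_c = .data$c_post - .data$c_prior,
      d_ln_aa = .data$ln_aa_post - .data$ln_aa_prior,
      ln_t_mean = mean2(.data$ln_t_prior, .data$ln_t_post),
      c_mean = mean2(.data$c_prior, .data$c_post),
      ln_aa_mean = mean2(.data$ln_aa_prior, .data$ln_aa_post),
      post_missing = is.na(.data$t_post) & is.na(.data$c_post)
    )
}

#' One-tailed paired t test
#'
#' Classical paired t on the differences `x - y` with `df = n - 1` and a
#' one-tailed p value in the stated direction, after pairwise-complete
#' filtering.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative `"greater"` tests mean(x - y) > 0, `"less"` the reverse.
#' @return Tibble `t`, `df`, `p`, `n`, `mean_diff`.
#' @export
paired_t_one_tailed <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) stop("zero variance of paired differences", call. = FALSE)
  tval <- mean(d) / (s / sqrt(n))
  p <- if (alternative == "greater") {
    stats::pt(tval, n - 1, lower.tail = FALSE)
  } else {
    stats::pt(tval, n - 1)
  }
  tibble::tibble(t = tval, df = n - 1, p = p, n = n, mean_diff = mean(d))
}

#' Pearson product-moment correlation (pairwise complete)
#'
#' @param x,y numeric vectors of equal length.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("zero variance", call. = FALSE)
  }
  stats::cor(x[ok], y[ok])
}

#' Post-hoc power of the joint F test of a multiple regression
#'
#' Computes Cohen's effect size `f2 = R2 / (1 - R2)`, the noncentrality
#' `lambda = f2 * N` (the convention that treats the total sample size as the
#' noncentrality multiplier; `convention = "error"` uses `f2 * df2` instead),
#' and the power as the upper-tail mass of the noncentral F beyond the
#' central critical value with `df1 = n_predictors`,
#' `df2 = N - n_predictors - 1`. At `R2 = 0` the power equals `alpha`.
#'
#' @param r2 observed squared multiple correlation, in `[0, 1)`.
#' @param n total sample size; must exceed `n_predictors + 1`.
#' @param n_predictors number of predictors in the joint test.
#' @param alpha test size.
#' @param convention noncentrality convention, `"n"` (default) or `"error"`.
#' @return A one-row tibble of class `power_result`: `r2`, `f2`, `lambda`,
#'   `df1`, `df2`, `alpha`, `power`, `cohen_label`.
#' @export
posthoc_power_f <- function(r2, n, n_predictors, alpha = 0.05,
                            convention = c("n", "error")) {
  convention <- match.arg(convention)
  if (!is.finite(r2) || r2 < 0 || r2 >= 1) stop("r2 must be in [0, 1)", call. = FALSE)
  if (n <= n_predictors + 1) stop("n must exceed n_predictors + 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  f2 <- r2 / (1 - r2)
  df1 <- n_predictors
  df2 <- n - n_predictors - 1
  lambda <- f2 * switch(convention, n = n, error = df2)
  crit <- stats::qf(1 - alpha, df1, df2)
  power <- stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
  label <- if (f2 >= 0.35) "large" else if (f2 >= 0.15) "medium" else if (f2 >= 0.02) "small" else "negligible"
  out <- tibble::tibble(r2 = r2, f2 = f2, lambda = lambda, df1 = df1,
                        df2 = df2, alpha = alpha, power = power,
                        cohen_label = label)
  class(out) <- c("power_result", class(out))
  out
}

#' Proportions of subjects showing the expected stress directions
#'
#' For each study and for both combined: the percentage of subjects whose
#' speaking/listening TBV ratio is strictly below 1, whose speaking/listening
#' pulse ratio is strictly above 1, and who show *both* a faster pulse and a
#' lower TBV during conversation than during the video. Subjects with a
#' missing ratio are excluded from that denominator.
#'
#' @param metrics per-subject metrics with columns `study`,
#'   `tbv_speak_listen`, `pulse_speak_listen`, `tbv_conv_video`, `bpm_video`,
#'   `bpm_conversation`.
#' @return Tidy tibble: `study`, `measure`, `n`, `k`, `percent`.
#' @export
proportion_summary <- function(metrics) {
  if (nrow(metrics) == 0) stop("no subjects with computed ratios", call. = FALSE)
  one <- function(d, study_label) {
    mk <- function(measure, flag) {
      ok <- !is.na(flag)
      tibble::tibble(study = study_label, measure = measure,
                     n = sum(ok), k = sum(flag[ok]),
                     percent = 100 * sum(flag[ok]) / max(sum(ok), 1))
    }
    dplyr::bind_rows(
      mk("tbv_speak_listen_lt1", d$tbv_speak_listen < 1),
      mk("pulse_speak_listen_gt1", d$pulse_speak_listen > 1),
      mk("both_conv_effects",
         d$bpm_conversation > d$bpm_video & d$tbv_conv_video < 1)
    )
  }
  per_study <- metrics |>
    dplyr::group_by(.data$study) |>
    dplyr::group_map(~ one(.x, as.character(.y$study[[1]]))) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per_study, one(metrics, "combined"))
}
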