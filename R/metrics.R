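#' Signal-to-noise ratio of gesture EMG around cues
#'
#' For each cue and channel, power is the mean squared amplitude after
#' mean removal (i.e. the variance) inside a cue-relative window, and
#' `SNR = 10 log10(P_signal / P_noise)` in dB. The defaults follow the
#' event design of a 3 s rest / 3 s gesture protocol: noise from -3..-1 s
#' before the cue (rest, excluding the last second where anticipatory
#' activity may appear), signal from +1..+3 s after it (steady gesture,
#' excluding the reaction onset).
#'
#' Per-(channel, gesture) values average a gesture's cues; the pooled
#' summary (mean +/- SD over all channel x gesture pairs) mirrors how a
#' single SNR figure is quoted for a whole device.
#'
#' @param rec An [emg_recording].
#' @param cues A [cue_schedule]; both windows must fall inside the
#'   recording for every cue.
#' @param noise_window,signal_window Cue-relative `(start, end)` windows,
#'   seconds.
#' @return An `emg_snr` object: tibble `per_channel_gesture` (columns
#'   `channel`, `gesture`, `snr_db`), vector `pooled`, and `summary`
#'   (`mean_db`, `sd_db`).
#' @examples
#' sess <- generate_recording(synth_config(trials = 1, powerline_amp = 0))
#' snr_db(sess$recording, sess$cues)
#' @export
snr_db <- function(rec, cues, noise_window = c(-3, -1), signal_window = c(1, 3)) {
  stopifnot(is_emg_recording(rec))
  check_window <- function(w, nm) {
    if (length(w) != 2 || diff(w) <= 0) {
      stop_emg("invalid_window", "`", nm, "` must be an increasing pair")
    }
  }
  check_window(noise_window, "noise_window")
  check_window(signal_window, "signal_window")
  N <- n_samples(rec)

  win_power <- function(onset, w) {
    s0 <- round((onset + w[1] - rec$t0) * rec$rate) + 1
    s1 <- round((onset + w[2] - rec$t0) * rec$rate)
    if (s0 < 1 || s1 > N) {
      stop_emg("window_outside_recording",
               "cue-relative window [", w[1], ", ", w[2], "] s falls outside the recording")
    }
    apply(rec$samples[, s0:s1, drop = FALSE], 1L, stats::var)
  }

  rows <- purrr::map_dfr(seq_len(nrow(cues)), function(i) {
    pn <- win_power(cues$onset_s[i], noise_window)
    ps <- win_power(cues$onset_s[i], signal_window)
    if (any(pn == 0)) stop_emg("zero_noise_power", "noise window has zero power (cue ", i, ")")
    tibble::tibble(channel = rec$channel_names, gesture = cues$label[i],
                   cue = i, snr_db = 10 * log10(ps / pn))
  })
  per_cg <- rows |>
    dplyr::group_by(.data$channel, .data$gesture) |>
    dplyr::summarise(snr_db = mean(.data$snr_db), .groups = "drop")
  pooled <- per_cg$snr_db
  structure(
    list(per_channel_gesture = per_cg, pooled = pooled,
         summary = c(mean_db = mean(pooled), sd_db = stats::sd(pooled)),
         noise_window = noise_window, signal_window = signal_window),
    class = "emg_snr"
  )
}

#' @export
print.emg_snr <- function(x, ...) {
  cat(sprintf("<emg_snr> %.2f +/- %.2f dB over %d channel x gesture pairs\n",
              x$summary["mean_db"], x$summary["sd_db"], length(x$pooled)))
  invisible(x)
}

#' Normality-gated paired comparison
#'
#' Compares two paired samples the way biosignal studies commonly do: a
#' Kolmogorov-Smirnov-type normality check on the paired differences
#' decides between a paired t-test (normality not rejected) and the
#' Wilcoxon signed-rank test. Because the mean and SD of the differences
#' are estimated from the sample, the gate uses the Lilliefors-corrected
#' KS statistic rather than naive KS critical values.
#'
#' If all differences are zero the comparison is degenerate: no test can
#' be run, and the result says so rather than reporting spurious
#' (non-)significance.
#'
#' @param a,b Numeric vectors of equal length >= 3 (paired observations).
#' @param alpha Gate level for the normality check (default 0.05).
#' @return An `emg_comparison` list: `test_name`, `statistic`, `p_value`,
#'   `normality_p`, `decision_rule_applied`, `n`, `mean_difference`.
#' @examples
#' paired_comparison(rnorm(20, 1), rnorm(20))
#' @export
paired_comparison <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop_emg("length_mismatch", "paired samples differ in length")
  if (length(a) < 3) stop_emg("too_few_samples", "need >= 3 pairs")
  d <- a - b
  if (all(d == 0)) {
    return(structure(
      list(test_name = "degenerate", statistic = NA_real_, p_value = NA_real_,
           normality_p = NA_real_,
           decision_rule_applied = "all paired differences are zero; no test performed",
           n = length(d), mean_difference = 0),
      class = "emg_comparison"
    ))
  }
  # Lilliefors needs n >= 5; for tiny samples fall back to Shapiro-Wilk
  normality_p <- if (stats::sd(d) == 0) 0
  else if (length(d) >= 5) nortest::lillie.test(d)$p.value
  else stats::shapiro.test(d)$p.value
  if (normality_p > alpha) {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(test_name = "paired t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value)
    rule <- sprintf("normality not rejected (KS-Lilliefors p = %.3g > %.2f): paired t-test",
                    normality_p, alpha)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
    res <- list(test_name = "Wilcoxon signed rank", statistic = unname(wt$statistic),
                p_value = wt$p.value)
    rule <- sprintf("normality rejected (KS-Lilliefors p = %.3g <= %.2f): Wilcoxon signed rank",
                    normality_p, alpha)
  }
  structure(
    c(res, list(normality_p = normality_p, decision_rule_applied = rule,
                n = length(d), mean_difference = mean(d))),
    class = "emg_comparison"
  )
}

#' @export
print.emg_comparison <- function(x, ...) {
  cat(sprintf("<emg_comparison> %s: statistic %.4g, p = %.4g (n = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n))
  cat(" ", x$decision_rule_applied, "\n")
  invisible(x)
}
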