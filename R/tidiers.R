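#' Tidy a cross-validation report
#'
#' @param x An `emg_report` from [cross_validate_trials()].
#' @param ... Unused.
#' @return A tibble with one row per fold: `fold`, `test_trial`,
#'   `accuracy`, `n_test`.
#' @method tidy emg_report
#' @export
tidy.emg_report <- function(x, ...) {
  tibble::tibble(
    fold = seq_along(x$per_fold_accuracies),
    test_trial = vapply(x$folds, function(f) as.integer(f$test_trial), integer(1)),
    accuracy = x$per_fold_accuracies,
    n_test = vapply(x$folds, function(f) f$n_test, integer(1))
  )
}

#' @rdname tidy.emg_report
#' @method glance emg_report
#' @export
glance.emg_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    mean_fold_accuracy = x$mean_accuracy,
    sd_fold_accuracy = x$sd_accuracy,
    n_folds = length(x$per_fold_accuracies),
    n_windows = sum(x$confusion),
    protocol = x$protocol %||% NA_character_
  )
}

#' Confusion matrix as a long tibble
#'
#' @param x An `emg_report`.
#' @param normalize Divide each row by its true-class count (row
#'   proportions) when `TRUE`.
#' @return Tibble with columns `true`, `predicted`, `n` (or `prop`).
#' @export
confusion_tbl <- function(x, normalize = FALSE) {
  tab <- as.data.frame(x$confusion)
  names(tab) <- c("true", "predicted", "n")
  out <- tibble::as_tibble(tab)
  if (normalize) {
    out <- out |>
      dplyr::group_by(.data$true) |>
      dplyr::mutate(prop = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  out
}

#' Plot a confusion matrix heat map
#'
#' Row-normalized confusion heat map (rows = true gesture), the standard
#' display for multiclass gesture decoders.
#'
#' @param object An `emg_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emg_report
#' @export
autoplot.emg_report <- function(object, ...) {
  dat <- confusion_tbl(object, normalize = TRUE)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$predicted, y = .data$true,
                                    fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0,
                                                   sprintf("%.2f", .data$prop), "")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1), name = "row prop.") +
    ggplot2::scale_y_discrete(limits = rev(levels(dat$true))) +
    ggplot2::labs(x = "predicted gesture", y = "true gesture",
                  title = sprintf("Overall accuracy %.2f%%", 100 * object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Tidy methods for the classifier comparison table
#'
#' `tidy()` returns the table itself (it is already tidy); `autoplot()`
#' draws mean +/- SD accuracy per classifier family.
#'
#' @param x,object A `gesture_comparison` from [compare_classifiers()].
#' @param ... Unused.
#' @method tidy gesture_comparison
#' @export
tidy.gesture_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.gesture_comparison
#' @method autoplot gesture_comparison
#' @export
autoplot.gesture_comparison <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::mutate(classifier = factor(.data$classifier,
                                      levels = rev(.data$classifier)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_accuracy, y = .data$classifier)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mean_accuracy - .data$sd_accuracy,
                                         xmax = pmin(1, .data$mean_accuracy + .data$sd_accuracy)),
                            height = 0.3) +
    ggplot2::scale_x_continuous(limits = c(0, 1), labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "mean fold accuracy", y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy and plot SNR results
#'
#' @param x,object An `emg_snr` from [snr_db()].
#' @param ... Unused.
#' @return `tidy()`: the per-(channel, gesture) tibble; `glance()`: a
#'   one-row summary; `autoplot()`: a histogram of pooled SNR values.
#' @method tidy emg_snr
#' @export
tidy.emg_snr <- function(x, ...) {
  x$per_channel_gesture
}

#' @rdname tidy.emg_snr
#' @method glance emg_snr
#' @export
glance.emg_snr <- function(x, ...) {
  tibble::tibble(mean_db = unname(x$summary["mean_db"]),
                 sd_db = unname(x$summary["sd_db"]),
                 n = length(x$pooled))
}

#' @rdname tidy.emg_snr
#' @method autoplot emg_snr
#' @export
autoplot.emg_snr <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(snr_db = object$pooled),
                  ggplot2::aes(x = .data$snr_db)) +
    ggplot2::geom_histogram(bins = 20, fill = "#4393c3", colour = "white") +
    ggplot2::labs(x = "SNR (dB)", y = "count",
                  title = sprintf("SNR %.2f +/- %.2f dB",
                                  object$summary["mean_db"], object$summary["sd_db"])) +
    ggplot2::theme_minimal()
}

#' Tidy a paired comparison
#'
#' @param x An `emg_comparison` from [paired_comparison()].
#' @param ... Unused.
#' @return One-row tibble: `test_name`, `statistic`, `p_value`,
#'   `normality_p`, `n`, `mean_difference`.
#' @method tidy emg_comparison
#' @export
tidy.emg_comparison <- function(x, ...) {
  tibble::tibble(test_name = x$test_name, statistic = x$statistic,
                 p_value = x$p_value, normality_p = x$normality_p,
                 n = x$n, mean_difference = x$mean_difference)
}

#' Plot a short excerpt of a recording
#'
#' Stacked per-channel traces with optional cue onset markers; intended
#' for fixture-sized excerpts, not full sessions.
#'
#' @param object An [emg_recording].
#' @param cues Optional [cue_schedule]: onsets drawn as vertical lines.
#' @param ... Unused.
#' @method autoplot emg_recording
#' @export
autoplot.emg_recording <- function(object, cues = NULL, ...) {
  dat <- as_tibble(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (uV)") +
    ggplot2::theme_minimal()
  if (!is.null(cues)) {
    p <- p + ggplot2::geom_vline(data = tibble::tibble(onset = cues$onset_s),
                                 ggplot2::aes(xintercept = .data$onset),
                                 linetype = "dashed", colour = "#b2182b")
  }
  p
}
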