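#' Cut a recording into labelled overlapping windows
#'
#' For every cue, fixed-length windows are slid across the cue-relative
#' label window (default 0..3 s after onset, the instructed-gesture period)
#' at stride `hop = round(window_samples * (1 - overlap))` (minimum 1).
#' Window starts are exactly `0, hop, 2*hop, ...` samples into the label
#' window; a window is kept only if it lies entirely inside it, so the
#' count per cue is `floor((L - W) / hop) + 1` (L = label-window length in
#' samples, W = window length). Every window carries its cue's label and
#' trial; windows never straddle a rest/gesture boundary.
#'
#' With the defaults of a 2000 Hz recording, a 300 ms window is 600 samples
#' and 96% overlap gives a 24-sample hop, i.e. 226 windows per 3 s cue.
#'
#' @param rec An [emg_recording] (normally already filtered).
#' @param cues A [cue_schedule].
#' @param window_ms Window length, milliseconds (default 300).
#' @param overlap Fractional overlap between consecutive windows, in
#'   `[0, 1)` (default 0.96).
#' @param label_window Numeric length-2: cue-relative start/end of the
#'   labelled period, seconds (default `c(0, 3)`).
#' @return An `emg_segments` object: list with `windows` (list of
#'   channels x window_samples matrices), `label`, `cue_index`, `trial`,
#'   `start_time` (vectors aligned with `windows`), plus `window_samples`,
#'   `hop_samples`, `rate`, and the label vocabulary.
#' @examples
#' synth <- generate_recording(synth_config(trials = 1, gestures = c("I", "F")))
#' seg <- segment_windows(synth$recording, synth$cues)
#' seg
#' @export
segment_windows <- function(rec, cues, window_ms = 300, overlap = 0.96,
                            label_window = c(0, 3)) {
  stopifnot(is_emg_recording(rec))
  if (!(overlap >= 0 && overlap < 1)) {
    stop_emg("invalid_overlap", "`overlap` must be in [0, 1)")
  }
  if (length(label_window) != 2 || diff(label_window) <= 0) {
    stop_emg("invalid_label_window", "`label_window` must be an increasing pair")
  }
  W <- round(window_ms * rec$rate / 1000)
  if (W < 2) stop_emg("invalid_label_window", "window shorter than 2 samples")
  hop <- max(1L, as.integer(round(W * (1 - overlap))))
  N <- n_samples(rec)

  windows <- list(); lab <- character(); cue_i <- integer()
  trial <- integer(); start_t <- numeric()
  for (i in seq_len(nrow(cues))) {
    on <- cues$onset_s[i]
    s0 <- round((on + label_window[1] - rec$t0) * rec$rate) + 1  # 1-based
    s1 <- round((on + label_window[2] - rec$t0) * rec$rate)
    s0 <- max(s0, 1L); s1 <- min(s1, N)
    L <- s1 - s0 + 1
    if (L < W) {
      warning(sprintf("cue %d (%s): label window (%d samples) shorter than one window; skipped",
                      i, cues$label[i], max(L, 0)), call. = FALSE)
      next
    }
    starts <- seq.int(0L, L - W, by = hop)
    for (st in starts) {
      windows[[length(windows) + 1L]] <- rec$samples[, (s0 + st):(s0 + st + W - 1), drop = FALSE]
      lab <- c(lab, cues$label[i])
      cue_i <- c(cue_i, i)
      trial <- c(trial, cues$trial[i])
      start_t <- c(start_t, rec$t0 + (s0 + st - 1) / rec$rate)
    }
  }
  structure(
    list(windows = windows, label = lab, cue_index = cue_i, trial = trial,
         start_time = start_t, window_samples = as.integer(W),
         hop_samples = hop, rate = rec$rate,
         label_set = label_set(cues) %||% unique(cues$label)),
    class = "emg_segments"
  )
}

#' @export
print.emg_segments <- function(x, ...) {
  cat(sprintf("<emg_segments> %d windows of %d samples (hop %d) @ %g Hz\n",
              length(x$windows), x$window_samples, x$hop_samples, x$rate))
  if (length(x$label)) print(table(label = x$label))
  invisible(x)
}

#' @export
length.emg_segments <- function(x) length(x$windows)

#' Segment metadata as a tibble
#'
#' One row per window: `label`, `cue_index`, `trial`, `start_time`. The
#' windows themselves stay in the `emg_segments` object.
#' @param x An `emg_segments`.
#' @param ... Unused.
#' @method as_tibble emg_segments
#' @export
as_tibble.emg_segments <- function(x, ...) {
  tibble::tibble(label = x$label, cue_index = x$cue_index,
                 trial = x$trial, start_time = x$start_time)
}

# subset windows by logical/integer index, preserving metadata
subset_segments <- function(seg, idx) {
  seg$windows <- seg$windows[idx]
  seg$label <- seg$label[idx]
  seg$cue_index <- seg$cue_index[idx]
  seg$trial <- seg$trial[idx]
  seg$start_time <- seg$start_time[idx]
  seg
}

#' Expected window count for a label window
#'
#' The deterministic tiling arithmetic used by [segment_windows()]:
#' `floor((L - W) / hop) + 1` windows fit, or 0 if `L < W`.
#'
#' @param length_samples Label-window length L, samples.
#' @param window_samples Window length W, samples.
#' @param hop_samples Stride, samples.
#' @return Integer window count.
#' @export
window_count <- function(length_samples, window_samples, hop_samples) {
  if (length_samples < window_samples) return(0L)
  as.integer(floor((length_samples - window_samples) / hop_samples) + 1L)
}
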