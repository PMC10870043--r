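#' Filter specifications
#'
#' Descriptions of the two Butterworth filtering stages applied to raw EMG:
#' a cascade of band-stop (notch) stages removing powerline interference at
#' the fundamental and its harmonics, and a band-pass retaining the surface
#' EMG band.
#'
#' `order` is the order handed to the Butterworth designer (an order-4
#' band-pass/band-stop design has 8 poles; zero-phase application squares
#' the magnitude response on top of that). The effective order is recorded
#' in the spec for transparency.
#'
#' @param fundamental Powerline fundamental frequency, Hz.
#' @param half_width Half-width of each stop band, Hz: stage k stops
#'   `k * fundamental +/- half_width`.
#' @param low,high Band-pass corner frequencies, Hz.
#' @param order Butterworth design order (even, >= 2).
#' @param zero_phase Apply forward-backward (`TRUE`, default, for offline
#'   analysis) or causal single-pass (`FALSE`, for streaming).
#' @return A `filter_spec` list.
#' @examples
#' powerline_spec()      # 60 Hz +/- 8, order 4
#' bandpass_spec()       # 20-450 Hz, order 4
#' @export
powerline_spec <- function(fundamental = 60, half_width = 8, order = 4,
                           zero_phase = TRUE) {
  check_order(order)
  if (half_width <= 0 || half_width >= fundamental) {
    stop_emg("invalid_filter", "half_width must be in (0, fundamental)")
  }
  structure(list(kind = "powerline_stop", fundamental = fundamental,
                 half_width = half_width, order = order,
                 effective_order = as.integer(2 * order * (1 + zero_phase)),
                 zero_phase = zero_phase),
            class = "filter_spec")
}

#' @rdname powerline_spec
#' @export
bandpass_spec <- function(low = 20, high = 450, order = 4, zero_phase = TRUE) {
  check_order(order)
  if (!(0 < low && low < high)) stop_emg("invalid_filter", "need 0 < low < high")
  structure(list(kind = "bandpass", low = low, high = high, order = order,
                 effective_order = as.integer(2 * order * (1 + zero_phase)),
                 zero_phase = zero_phase),
            class = "filter_spec")
}

check_order <- function(order) {
  if (length(order) != 1 || order < 2 || order %% 2 != 0) {
    stop_emg("invalid_filter", "`order` must be even and >= 2")
  }
}

#' Remove powerline interference and its harmonics
#'
#' Applies a cascade of Butterworth band-stop stages, one per harmonic
#' `k * fundamental` for k = 1..K, each stopping `+/- half_width` Hz around
#' its centre. K is the largest harmonic whose stop band lies entirely
#' below `max_freq` (default 450 Hz, the upper edge of the EMG band-pass:
#' higher harmonics are removed by that filter anyway). At 2000 Hz with a
#' 60 Hz fundamental this gives 7 stages (60, 120, ..., 420 Hz).
#'
#' @param rec An [emg_recording].
#' @param spec A `filter_spec` from [powerline_spec()].
#' @param max_freq Upper cap, Hz: harmonics whose stop band would cross it
#'   are not notched. Must keep every stop band below Nyquist.
#' @return A filtered `emg_recording` of identical shape, with attribute
#'   `"filters"` accumulating the specs applied.
#' @examples
#' rec <- emg_recording(matrix(sin(2 * pi * 60 * (0:7999) / 2000),
#'                             nrow = 2, ncol = 8000, byrow = TRUE), 2000)
#' quiet <- powerline_filter(rec)
#' @export
powerline_filter <- function(rec, spec = powerline_spec(), max_freq = 450) {
  stopifnot(is_emg_recording(rec), identical(spec$kind, "powerline_stop"))
  nyq <- rec$rate / 2
  K <- floor((min(max_freq, nyq) - spec$half_width) / spec$fundamental)
  if (K < 1) stop_emg("invalid_filter", "no harmonic stop band fits below ",
                      min(max_freq, nyq), " Hz")
  centres <- spec$fundamental * seq_len(K)
  if (max(centres) + spec$half_width >= nyq) {
    stop_emg("stopband_above_nyquist", "stop band crosses Nyquist (", nyq, " Hz)")
  }
  x <- rec$samples
  for (f0 in centres) {
    flt <- signal::butter(spec$order,
                          c(f0 - spec$half_width, f0 + spec$half_width) / nyq,
                          type = "stop")
    x <- apply_filter(x, flt, spec$zero_phase)
  }
  spec$harmonics <- centres
  finish_filter(rec, x, spec)
}

#' Band-pass filter a recording
#'
#' Butterworth band-pass retaining the surface-EMG band (default
#' 20-450 Hz): removes motion-artifact drift below `low` and out-of-band
#' noise above `high`.
#'
#' @inheritParams powerline_filter
#' @param spec A `filter_spec` from [bandpass_spec()].
#' @return A filtered `emg_recording` of identical shape.
#' @export
bandpass_filter <- function(rec, spec = bandpass_spec()) {
  stopifnot(is_emg_recording(rec), identical(spec$kind, "bandpass"))
  nyq <- rec$rate / 2
  if (spec$high >= nyq) stop_emg("stopband_above_nyquist",
                                 "band-pass upper edge must be below Nyquist")
  flt <- signal::butter(spec$order, c(spec$low, spec$high) / nyq, type = "pass")
  x <- apply_filter(rec$samples, flt, spec$zero_phase)
  finish_filter(rec, x, spec)
}

#' Default preprocessing: powerline notch cascade then band-pass
#'
#' Convenience wrapper applying [powerline_filter()] followed by
#' [bandpass_filter()] with the shipped defaults.
#'
#' @inheritParams powerline_filter
#' @param powerline,bandpass Filter specs for the two stages.
#' @return A filtered `emg_recording`.
#' @export
preprocess_recording <- function(rec, powerline = powerline_spec(),
                                 bandpass = bandpass_spec()) {
  rec |>
    powerline_filter(powerline, max_freq = bandpass$high) |>
    bandpass_filter(bandpass)
}

apply_filter <- function(x, flt, zero_phase) {
  out <- t(apply(x, 1L, function(ch) {
    if (zero_phase) as.numeric(signal::filtfilt(flt, ch))
    else as.numeric(signal::filter(flt, ch))
  }))
  if (!all(is.finite(out))) {
    stop_emg("filter_unstable", "non-finite filter output (unstable design)")
  }
  out
}

finish_filter <- function(rec, x, spec) {
  out <- emg_recording(x, rec$rate, rec$channel_names, rec$t0)
  attr(out, "filters") <- c(attr(rec, "filters"), list(spec))
  out
}

#' Analytic Butterworth band filter magnitude
#'
#' Closed-form magnitude response of a digital Butterworth band-pass or
#' band-stop designed by bilinear transform: the analog prototype magnitude
#' `1 / sqrt(1 + Omega^(2n))` evaluated at the warped, band-transformed
#' frequency. Useful for verifying a designed filter against theory.
#'
#' @param f Frequencies, Hz, at which to evaluate.
#' @param low,high Band edges, Hz.
#' @param order Design order n.
#' @param rate Sampling rate, Hz.
#' @param type `"pass"` or `"stop"`.
#' @return Numeric vector of single-pass amplitude gains (zero-phase
#'   application squares these).
#' @export
butterworth_gain <- function(f, low, high, order, rate, type = c("pass", "stop")) {
  type <- match.arg(type)
  v <- tan(pi * f / rate)
  vl <- tan(pi * low / rate)
  vh <- tan(pi * high / rate)
  omega <- (v^2 - vl * vh) / (v * (vh - vl))
  if (type == "stop") omega <- 1 / omega
  1 / sqrt(1 + omega^(2 * order))
}
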