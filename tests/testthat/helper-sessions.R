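# Shared fixtures, generated in code and cached for the test run.

.session_cache <- new.env(parent = emptyenv())

# small 4-gesture, 2-trial session: fast but fully representative
small_session <- function(seed = 3, separation = 2, trials = 2,
                          gestures = c("I", "L", "F", "S")) {
  key <- paste("sess", seed, separation, trials, paste(gestures, collapse = ""),
               sep = "_")
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- generate_recording(
      synth_config(trials = trials, gestures = gestures,
                   separation = separation, seed = seed)
    )
  }
  .session_cache[[key]]
}

# filtered + lightly overlapped segmentation of the small session
small_segments <- function(seed = 3, separation = 2, trials = 2,
                           gestures = c("I", "L", "F", "S"), overlap = 0.8) {
  key <- paste("seg", seed, separation, trials, paste(gestures, collapse = ""),
               overlap, sep = "_")
  if (is.null(.session_cache[[key]])) {
    sess <- small_session(seed, separation, trials, gestures)
    rec <- preprocess_recording(sess$recording)
    .session_cache[[key]] <- segment_windows(rec, sess$cues, overlap = overlap)
  }
  .session_cache[[key]]
}

# random SPD matrix via A A' + eps I
random_spd <- function(C, scale = 1) {
  A <- matrix(rnorm(C * C), C, C)
  scale * (tcrossprod(A) + diag(0.5, C))
}

# steady-state RMS of the middle half of a signal
mid_rms <- function(x) {
  n <- length(x)
  sd(x[floor(n / 4):floor(3 * n / 4)])
}

# single-frequency amplitude estimate by quadrature correlation over the
# middle half of the signal (independent of the filtering code under test)
tone_amplitude <- function(x, f, rate) {
  n <- length(x)
  idx <- floor(n / 4):floor(3 * n / 4)
  tt <- (idx - 1) / rate
  2 * sqrt(mean(x[idx] * sin(2 * pi * f * tt))^2 +
             mean(x[idx] * cos(2 * pi * f * tt))^2)
}
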