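#' Configuration for the synthetic EMG generator
#'
#' Describes a simulated recording session: trial structure (per cue, 3 s
#' of idle rest followed by 3 s of instructed gesture), channel count and
#' sampling rate of an 8-channel 2000 Hz forearm array, the gesture
#' vocabulary, and the noise model. The EMG carrier is band-limited
#' (20-450 Hz) Gaussian noise whose per-channel amplitude and cross-channel
#' mixing depend on the gesture, so each gesture has a distinct theoretical
#' spatial covariance; powerline interference (60 Hz + harmonics) and
#' broadband baseline noise are added on top. The `separation` knob scales
#' how far apart the class covariances sit on the SPD manifold: 0 makes
#' all gestures statistically identical (chance-level decoding), the
#' default 2 makes them comfortably separable.
#'
#' @param n_channels Number of electrodes (default 8).
#' @param rate Sampling rate, Hz (default 2000).
#' @param gestures Gesture vocabulary (default [gesture_labels()], 10
#'   labels; the first is treated as idle/rest).
#' @param trials Number of trials; each trial presents every gesture once
#'   in a seeded random order (default 3).
#' @param rest_s,gesture_s Rest and gesture durations per cue, seconds
#'   (defaults 3 and 3).
#' @param band EMG carrier band, Hz (default `c(20, 450)`).
#' @param powerline_amp Powerline amplitude, uV (default 20).
#' @param powerline_harmonics Number of harmonics including the
#'   fundamental (default 3).
#' @param baseline_noise_amp Baseline white-noise RMS, uV (default 5).
#' @param base_activation Idle-state carrier RMS per channel, uV
#'   (default 30; gesture channels modulate around this up to ~100 uV at
#'   the default separation).
#' @param separation Non-negative scalar scaling inter-class covariance
#'   differences (default 2).
#' @param seed Integer seed; the whole session is reproducible from it.
#' @return A `synth_config` list (validated).
#' @export
synth_config <- function(n_channels = 8, rate = 2000, gestures = gesture_labels(),
                         trials = 3, rest_s = 3, gesture_s = 3,
                         band = c(20, 450), powerline_amp = 20,
                         powerline_harmonics = 3, baseline_noise_amp = 5,
                         base_activation = 30, separation = 2, seed = 1) {
  cfg <- list(n_channels = as.integer(n_channels), rate = rate,
              gestures = as.character(gestures), trials = as.integer(trials),
              rest_s = rest_s, gesture_s = gesture_s, band = band,
              powerline_amp = powerline_amp,
              powerline_harmonics = as.integer(powerline_harmonics),
              baseline_noise_amp = baseline_noise_amp,
              base_activation = base_activation,
              separation = separation, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_channels < 2) stop_emg("invalid_config", "need >= 2 channels")
  if (cfg$rate <= 0) stop_emg("invalid_config", "rate must be positive")
  if (length(cfg$gestures) < 1 || anyDuplicated(cfg$gestures)) {
    stop_emg("invalid_config", "gestures must be a non-empty set of unique labels")
  }
  if (cfg$trials < 1) stop_emg("invalid_config", "trials must be >= 1")
  if (cfg$band[2] >= cfg$rate / 2) stop_emg("invalid_config", "band high must be below Nyquist")
  if (cfg$separation < 0) stop_emg("invalid_config", "separation must be >= 0")
  if (cfg$powerline_amp < 0 || cfg$baseline_noise_amp < 0 || cfg$base_activation < 0) {
    stop_emg("invalid_config", "amplitudes must be >= 0")
  }
  invisible(cfg)
}

#' Per-gesture activation profiles and mixing matrices
#'
#' Builds the class-conditional covariance structure the generator uses:
#' for gesture g, a per-channel amplitude profile
#' `a_g = base * exp(separation * z_g)` and a symmetric mixing matrix
#' `B_g = expm(separation/2 * S_g)`, with `z_g` and `S_g` fixed random
#' patterns drawn once from `seed` (the idle gesture keeps `z = 0`,
#' `S = 0`). The theoretical covariance of the gesture carrier is then
#' `Sigma_g = D_a B_g B_g' D_a + baseline^2 I`, so at separation 0 all
#' classes coincide and pairwise AIRM distances grow with separation.
#'
#' @param n_channels Channel count.
#' @param gestures Gesture labels (first = idle).
#' @param separation Non-negative class-separation scalar.
#' @param seed Integer seed for the fixed patterns.
#' @param base_activation,baseline_noise_amp Amplitude scales, uV.
#' @return A list with `profiles` (gesture -> amplitude vector, uV),
#'   `mixing` (gesture -> C x C matrix), and `covariances` (gesture ->
#'   theoretical SPD covariance of the modelled signal).
#' @export
default_profiles <- function(n_channels, gestures, separation, seed,
                             base_activation = 30, baseline_noise_amp = 5) {
  if (separation < 0) stop_emg("invalid_config", "separation must be >= 0")
  C <- n_channels
  profiles <- list(); mixing <- list(); covariances <- list()
  for (k in seq_along(gestures)) {
    g <- gestures[k]
    # per-gesture deterministic pattern, independent of the other gestures
    set.seed(seed * 1009L + k)
    if (k == 1) {
      # idle/rest: a flat, quieter profile (resting muscle tone). The constant
      # -0.7 pattern keeps idle on the common a = base * exp(separation * z)
      # form, so at separation 0 every class collapses to the same covariance
      # while at the default separation rest sits well below active gestures.
      z <- rep(-0.7, C)
      S <- matrix(0, C, C)
    } else {
      z <- stats::rnorm(C, sd = 0.45)
      A <- matrix(stats::rnorm(C * C, sd = 0.12), C, C)
      S <- (A + t(A)) / 2
    }
    a <- base_activation * exp(separation * z)
    B <- expm_sym(separation / 2 * S)
    profiles[[g]] <- a
    mixing[[g]] <- B
    sig <- diag(a) %*% tcrossprod(B) %*% diag(a) + diag(baseline_noise_amp^2, C)
    covariances[[g]] <- structure((sig + t(sig)) / 2,
                                  class = c("spd_matrix", "matrix", "array"))
  }
  list(profiles = profiles, mixing = mixing, covariances = covariances)
}

#' Generate a synthetic multichannel EMG session
#'
#' Simulates a full recording: for each trial, the gestures are presented
#' once each in seeded random order, each presentation being `rest_s`
#' seconds of idle activity followed by `gesture_s` seconds of the
#' gesture's carrier (cue onset = start of the gesture period). Per
#' channel, the signal is `a_gc * [B_g n(t)]_c + powerline(t) + e(t)`:
#' `n(t)` are independent unit-variance Gaussian carriers band-shaped to
#' `cfg$band` and renormalized to unit variance, `powerline` is a sum of
#' fixed-phase sinusoids at the mains fundamental and harmonics, `e(t)` is
#' white baseline noise. Everything is reproducible from `cfg$seed`.
#'
#' @param cfg A [synth_config].
#' @return A list of class `synth_session`:
#' \describe{
#'   \item{recording}{the [emg_recording] (unfiltered, contaminated)}
#'   \item{cues}{the [cue_schedule] (one cue per gesture per trial)}
#'   \item{truth}{ground truth: per-gesture theoretical covariances
#'     (of the carrier + baseline, i.e. post powerline removal), the
#'     activation profiles and mixing matrices, and the seed}
#' }
#' @examples
#' sess <- generate_recording(synth_config(trials = 1, gestures = c("I", "F", "S")))
#' sess$recording
#' @export
generate_recording <- function(cfg = synth_config()) {
  validate_synth_config(cfg)
  C <- cfg$n_channels
  fs <- cfg$rate
  prof <- default_profiles(C, cfg$gestures, cfg$separation, cfg$seed,
                           cfg$base_activation, cfg$baseline_noise_amp)

  n_rest <- round(cfg$rest_s * fs)
  n_gest <- round(cfg$gesture_s * fs)
  per_cue <- n_rest + n_gest
  n_cues <- cfg$trials * length(cfg$gestures)
  N <- n_cues * per_cue

  # carrier shaping filter + its exact gain so carriers stay unit-variance
  shape <- signal::butter(4, cfg$band / (fs / 2), type = "pass")
  gain <- carrier_gain(shape)

  set.seed(cfg$seed)
  order_per_trial <- lapply(seq_len(cfg$trials), function(t) sample(cfg$gestures))

  x <- matrix(0, C, N)
  onset <- numeric(n_cues); lab <- character(n_cues); tri <- integer(n_cues)
  i <- 0L
  for (t in seq_len(cfg$trials)) {
    for (g in order_per_trial[[t]]) {
      i <- i + 1L
      s0 <- (i - 1L) * per_cue            # 0-based block start
      onset[i] <- (s0 + n_rest) / fs
      lab[i] <- g
      tri[i] <- t - 1L

      idle <- cfg$gestures[1]
      x[, (s0 + 1):(s0 + n_rest)] <-
        carrier_block(n_rest, prof$profiles[[idle]], prof$mixing[[idle]], shape, gain)
      x[, (s0 + n_rest + 1):(s0 + per_cue)] <-
        carrier_block(n_gest, prof$profiles[[g]], prof$mixing[[g]], shape, gain)
    }
  }

  if (cfg$baseline_noise_amp > 0) {
    x <- x + matrix(stats::rnorm(C * N, sd = cfg$baseline_noise_amp), C, N)
  }
  if (cfg$powerline_amp > 0 && cfg$powerline_harmonics > 0) {
    tt <- (seq_len(N) - 1) / fs
    phases <- matrix(stats::runif(C * cfg$powerline_harmonics, 0, 2 * pi),
                     C, cfg$powerline_harmonics)
    for (k in seq_len(cfg$powerline_harmonics)) {
      amp <- cfg$powerline_amp / k        # harmonics roll off as 1/k
      x <- x + amp * sin(outer(phases[, k], rep(1, N)) +
                           outer(rep(2 * pi * 60 * k, C), tt))
    }
  }

  rec <- emg_recording(x, fs)
  cues <- cue_schedule(data.frame(onset_s = onset, label = lab, trial = tri),
                       label_set = cfg$gestures)
  structure(
    list(recording = rec, cues = cues,
         truth = list(covariances = prof$covariances,
                      profiles = prof$profiles, mixing = prof$mixing,
                      config = cfg, seed = cfg$seed)),
    class = "synth_session"
  )
}

# one block of band-shaped, mixed, amplitude-modulated carrier
carrier_block <- function(n, a, B, shape, gain) {
  C <- length(a)
  pad <- 400L                             # absorb filter edge transient
  n0 <- matrix(stats::rnorm(C * (n + 2L * pad)), C, n + 2L * pad)
  shaped <- t(apply(n0, 1L, function(ch) as.numeric(signal::filtfilt(shape, ch)))) / gain
  shaped <- shaped[, (pad + 1L):(pad + n), drop = FALSE]
  a * (B %*% shaped)                      # D_a B n, row-recycled product
}

# steady-state RMS gain of zero-phase filtering applied to unit white noise:
# sqrt(sum(h2^2)) where h2 is the forward-backward impulse response
carrier_gain <- function(flt) {
  imp <- c(rep(0, 4096), 1, rep(0, 4096))
  h2 <- as.numeric(signal::filtfilt(flt, imp))
  sqrt(sum(h2^2))
}

#' @export
print.synth_session <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<synth_session> %d gestures x %d trials, %d ch @ %g Hz, separation %g, seed %d\n",
              length(cfg$gestures), cfg$trials, cfg$n_channels, cfg$rate,
              cfg$separation, cfg$seed))
  invisible(x)
}
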