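test_that("the generator is seed-deterministic and silence-capable", {
  cfg <- synth_config(trials = 1, gestures = c("I", "F"), seed = 9)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$cues$label, b$cues$label)

  other <- generate_recording(synth_config(trials = 1, gestures = c("I", "F"),
                                           seed = 10))
  expect_false(identical(a$recording$samples, other$recording$samples))

  silent <- generate_recording(
    synth_config(trials = 1, gestures = c("I", "F"), base_activation = 0,
                 powerline_amp = 0, baseline_noise_amp = 0)
  )
  expect_equal(max(abs(silent$recording$samples)), 0)
})

test_that("cue schedules follow the rest/gesture trial structure", {
  cfg <- synth_config(trials = 3, seed = 2)
  sess <- generate_recording(cfg)
  cues <- sess$cues
  expect_equal(nrow(cues), 30)                        # 10 gestures x 3 trials
  expect_identical(sort(unique(cues$trial)), 0:2)
  # each trial presents every gesture exactly once
  for (t in 0:2) {
    expect_setequal(cues$label[cues$trial == t], gesture_labels())
  }
  # onsets: first cue after 3 s rest, then every 6 s (3 rest + 3 gesture)
  expect_equal(cues$onset_s, seq(3, by = 6, length.out = 30))
  # recording long enough to hold the last gesture window
  expect_gte(n_samples(sess$recording) / sess$recording$rate,
             max(cues$onset_s) + 3)
})

test_that("an unmixed flat-profile class yields a near-diagonal SCM", {
  # separation 0 disables mixing and profile differences: carrier is
  # independent across channels, so a long-window SCM is ~ diagonal
  cfg <- synth_config(trials = 1, gestures = c("I", "F"), separation = 0,
                      gesture_s = 10, powerline_amp = 0,
                      baseline_noise_amp = 0, seed = 13)
  sess <- generate_recording(cfg)
  seg <- segment_windows(sess$recording, sess$cues, window_ms = 10000,
                         overlap = 0, label_window = c(0, 10))
  scm <- unclass(spatial_covariance(seg$windows[[which(seg$label == "F")[1]]], 0))
  off <- max(abs(scm[upper.tri(scm)]))
  expect_lte(off / min(diag(scm)), 0.05)              # N = 20000 samples
  # and the diagonal sits at the configured carrier power
  expect_equal(mean(diag(scm)), 30^2, tolerance = 0.1 * 30^2)
})

test_that("profiles collapse at separation 0 and spread with separation", {
  prof0 <- default_profiles(8, gesture_labels(), separation = 0, seed = 4)
  d0 <- sapply(prof0$covariances, function(p)
    airm_distance(p, prof0$covariances[[1]]))
  expect_lt(max(d0), 1e-10)                           # all classes identical

  prof1 <- default_profiles(8, gesture_labels(), separation = 1, seed = 4)
  prof3 <- default_profiles(8, gesture_labels(), separation = 3, seed = 4)
  min_pair <- function(covs) {
    K <- length(covs)
    min(unlist(lapply(seq_len(K - 1), function(i)
      sapply((i + 1):K, function(j) airm_distance(covs[[i]], covs[[j]])))))
  }
  expect_gt(min_pair(prof3$covariances), min_pair(prof1$covariances))

  for (a in prof3$profiles) {
    expect_length(a, 8)
    expect_true(all(a >= 0))
  }
  # theoretical covariances are SPD
  for (p in prof3$covariances) {
    expect_gt(min(eigen(p, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("empirical gesture SCMs converge to the stored ground truth", {
  # relative Frobenius error <= 10% on 3 s windows, <= 3% on 30 s windows
  errs3 <- unlist(lapply(1:2, function(seed) {
    sess <- generate_recording(synth_config(trials = 1, powerline_amp = 0,
                                            seed = seed))
    seg <- segment_windows(sess$recording, sess$cues, window_ms = 3000,
                           overlap = 0)
    sapply(c("F", "S", "L"), function(g) {
      emp <- spatial_covariance(seg$windows[[which(seg$label == g)[1]]], 0)
      theo <- sess$truth$covariances[[g]]
      norm(unclass(emp) - unclass(theo), "F") / norm(unclass(theo), "F")
    })
  }))
  expect_lt(max(errs3), 0.10)

  sess30 <- generate_recording(synth_config(trials = 1, gestures = c("I", "F"),
                                            gesture_s = 30, powerline_amp = 0,
                                            seed = 3))
  seg30 <- segment_windows(sess30$recording, sess30$cues, window_ms = 30000,
                           overlap = 0, label_window = c(0, 30))
  emp <- spatial_covariance(seg30$windows[[which(seg30$label == "F")[1]]], 0)
  theo <- sess30$truth$covariances[["F"]]
  expect_lt(norm(unclass(emp) - unclass(theo), "F") / norm(unclass(theo), "F"),
            0.03)
})

test_that("powerline contamination is injected and removable", {
  cfg <- synth_config(trials = 1, gestures = c("I", "F"), powerline_amp = 25,
                      powerline_harmonics = 1, seed = 6)
  sess <- generate_recording(cfg)
  x <- sess$recording$samples[1, ]
  amp_pre <- tone_amplitude(x, 60, 2000)
  expect_gt(amp_pre, 0.5 * 25)                  # the 60 Hz peak is present

  filtered <- powerline_filter(sess$recording)
  amp_post <- tone_amplitude(filtered$samples[1, ], 60, 2000)
  expect_lte(amp_post^2 / amp_pre^2, 0.01)      # >= 99% of 60 Hz power gone
})

test_that("invalid configurations are refused", {
  expect_error(synth_config(n_channels = 1), class = "emg_invalid_config")
  expect_error(synth_config(separation = -1), class = "emg_invalid_config")
  expect_error(synth_config(band = c(20, 1200)), class = "emg_invalid_config")
  expect_error(synth_config(trials = 0), class = "emg_invalid_config")
})
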