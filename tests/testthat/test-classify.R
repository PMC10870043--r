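test_that("the shipped SVM defaults carry the optimized cost and gamma", {
  sp <- classifier_spec("SVM")
  expect_equal(sp$params$cost, 1.09)
  expect_equal(sp$params$gamma, 1 / 72)
  expect_identical(length(default_classifier_specs()), 13L)
  expect_error(classifier_spec("CNN"))
})

test_that("a separable fit reproduces its training labels deterministically", {
  seg <- small_segments()
  pipe <- fit_pipeline(seg, seed = 5)
  pred <- predict(pipe, seg)
  expect_identical(pred, seg$label)            # separable -> perfect recall
  expect_true(all(pred %in% pipe$label_set))

  pipe2 <- fit_pipeline(seg, seed = 5)
  expect_identical(predict(pipe2, seg), pred)  # same data + seed -> identical
  expect_identical(unclass(pipe2$reference), unclass(pipe$reference))

  expect_identical(predict(pipe, list()), character(0))
  expect_error(predict(pipe, list(matrix(0, 3, 10))), class = "emg_dim_mismatch")
})

test_that("single-class training sets are rejected", {
  seg <- small_segments()
  only_f <- seg
  keep <- seg$label == "F"
  only_f$windows <- seg$windows[keep]
  only_f$label <- seg$label[keep]
  only_f$trial <- seg$trial[keep]
  only_f$cue_index <- seg$cue_index[keep]
  only_f$start_time <- seg$start_time[keep]
  expect_error(fit_pipeline(only_f), class = "emg_single_class")
})

test_that("probes drawn from a class covariance recover that label", {
  # windows sampled directly from each gesture's theoretical covariance at
  # high separation classify back to their class in >= 95% of cases
  gaussian_segments <- function(covs, n_per_class, n_time, trial = 0L) {
    windows <- list(); labels <- character()
    for (g in names(covs)) {
      shape <- t(chol(unclass(covs[[g]])))
      for (i in seq_len(n_per_class)) {
        windows[[length(windows) + 1L]] <- shape %*% matrix(rnorm(8 * n_time), 8)
        labels <- c(labels, g)
      }
    }
    structure(list(windows = windows, label = labels,
                   cue_index = seq_along(labels),
                   trial = rep(trial, length(labels)),
                   start_time = seq_along(labels) * 0.1,
                   window_samples = n_time, hop_samples = n_time,
                   rate = 2000, label_set = names(covs)),
              class = "emg_segments")
  }
  hit_rates <- sapply(0:4, function(seed) {
    covs <- default_profiles(8, c("I", "L", "F", "S"), separation = 2,
                             seed = seed)$covariances
    set.seed(seed + 100)
    train <- gaussian_segments(covs, 30, 600)
    probe <- gaussian_segments(covs, 20, 600)
    pipe <- fit_pipeline(train, seed = seed)
    mean(predict(pipe, probe) == probe$label)
  })
  expect_gte(mean(hit_rates), 0.95)
})

test_that("leave-one-trial-out builds one fold per trial and aggregates", {
  sess <- small_session(trials = 3, gestures = gesture_labels())
  seg <- segment_windows(preprocess_recording(sess$recording), sess$cues,
                         overlap = 0.8)
  rpt <- cross_validate_trials(seg, seed = 2)
  expect_identical(length(rpt$per_fold_accuracies), 3L)       # 3 trials, 3 folds
  expect_gte(rpt$mean_accuracy, 0.95)

  # report invariants: row sums = true counts, accuracy = trace / total
  expect_identical(as.integer(rowSums(rpt$confusion)),
                   as.integer(table(factor(seg$label, levels = seg$label_set))))
  expect_equal(rpt$accuracy, sum(diag(rpt$confusion)) / sum(rpt$confusion))

  # tidiers
  td <- tidy(rpt)
  expect_identical(nrow(td), 3L)
  expect_equal(mean(td$accuracy), rpt$mean_accuracy)
  gl <- glance(rpt)
  expect_identical(gl$protocol, "leave_one_trial_out")
  expect_s3_class(autoplot(rpt), "ggplot")
})

test_that("train-first-test-rest scores each later trial separately", {
  seg <- small_segments(trials = 5, overlap = 0.6)
  rpt <- cross_validate_trials(seg, protocol = "train_first_test_rest", seed = 2)
  expect_identical(length(rpt$per_fold_accuracies), 4L)  # trials 1..4 vs trial 0
  expect_identical(vapply(rpt$folds, function(f) f$test_trial, numeric(1)),
                   as.numeric(1:4))
  expect_gte(rpt$mean_accuracy, 0.95)
  expect_error(
    cross_validate_trials(small_segments(trials = 1, seed = 4)),
    class = "emg_too_few_trials"
  )
})

test_that("majority vote per cue collapses window streams to cue decisions", {
  seg <- small_segments()
  rpt <- cross_validate_trials(seg, score = "cue_vote", seed = 2)
  expect_identical(sum(rpt$confusion), length(unique(seg$cue_index)))
})

test_that("no test-fold information leaks into per-fold fits", {
  seg <- small_segments()
  rpt1 <- cross_validate_trials(seg, seed = 7, keep_folds = TRUE)
  # drop one window belonging to the test trial of fold 1 (trial 0)
  drop <- which(seg$trial == 0)[5]
  seg2 <- seg
  seg2$windows <- seg$windows[-drop]
  seg2$label <- seg$label[-drop]
  seg2$trial <- seg$trial[-drop]
  seg2$cue_index <- seg$cue_index[-drop]
  seg2$start_time <- seg$start_time[-drop]
  rpt2 <- cross_validate_trials(seg2, seed = 7, keep_folds = TRUE)
  f1 <- rpt1$folds[[1]]; f2 <- rpt2$folds[[1]]
  expect_identical(unclass(f1$reference), unclass(f2$reference))
  expect_identical(f1$model$fit$coefs, f2$model$fit$coefs)
  expect_identical(f1$model$fit$SV, f2$model$fit$SV)
  expect_identical(f1$model$fit$rho, f2$model$fit$rho)
})

test_that("grid search is exhaustive with deterministic tie-breaking", {
  seg <- small_segments()
  covs <- lapply(seg$windows, spatial_covariance)
  feats <- tangent_map(covs, frechet_mean(covs))

  single <- grid_search_svm(feats, seg$label, grid = list(cost = 2, gamma = 0.5),
                            folds = 3, seed = 1)
  expect_equal(single$best$cost, 2)
  expect_equal(single$best$gamma, 0.5)

  grid <- list(cost = c(0.1, 1, 10), gamma = c(0.01, 0.1))
  res <- grid_search_svm(feats, seg$label, grid = grid, folds = 3, seed = 1)
  expect_identical(nrow(res$table), 6L)                  # exhaustive
  expect_equal(res$best$accuracy, max(res$table$accuracy))
  # separable data: every point perfect, tie-break -> smallest cost then gamma
  if (all(res$table$accuracy == 1)) {
    expect_equal(res$best$cost, 0.1)
    expect_equal(res$best$gamma, 0.01)
  }
  expect_error(grid_search_svm(feats, seg$label, folds = 1000),
               class = "emg_too_many_folds")
})

test_that("classifier comparison shares folds and never drops a family", {
  seg <- small_segments()
  specs <- list(classifier_spec("LDA"), classifier_spec("LDA"),
                classifier_spec("DT"))
  tab <- compare_classifiers(seg, specs, seed = 3)
  expect_s3_class(tab, "gesture_comparison")
  lda_rows <- tab[tab$classifier == "LDA", ]
  expect_identical(lda_rows$mean_accuracy[1], lda_rows$mean_accuracy[2])
  expect_true(all(diff(tab$mean_accuracy) <= 0))         # sorted descending
  expect_error(compare_classifiers(seg, list(classifier_spec("SVM"))),
               class = "emg_too_few_specs")

  # chance baseline on balanced labels
  expect_equal(dummy_accuracy(rep(gesture_labels(), 20)), 0.1)
})

test_that("accuracy tracks the class-separation of the generator", {
  # monotone non-decreasing mean accuracy over separations 0 < 1 < 2,
  # averaged over 3 seeds; chance at separation 0
  accs <- sapply(c(0, 1, 2), function(sep) {
    mean(sapply(10:12, function(seed) {
      seg <- small_segments(seed = seed, separation = sep, overlap = 0.6)
      cross_validate_trials(seg, seed = 1)$mean_accuracy
    }))
  })
  expect_true(all(diff(accs) >= -0.02))
  # 4 balanced classes: chance 0.25; cue-level binomial interval,
  # 3 seeds x 8 cues x 2 folds = 48 exchangeable units
  half <- 1.96 * sqrt(0.25 * 0.75 / 48)
  expect_gt(accs[1], 0.25 - half)
  expect_lt(accs[1], 0.25 + half)
  expect_gte(accs[3], 0.95)
})
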