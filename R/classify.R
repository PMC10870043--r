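#' Classifier specifications
#'
#' A `classifier_spec` names one of the 13 supported classifier families
#' and its hyperparameters. Families and engines:
#'
#' | name  | family                          | engine |
#' |-------|---------------------------------|--------|
#' | SVM   | RBF support vector machine (one-vs-one) | e1071 (libsvm) |
#' | kNN   | k-nearest neighbours            | class |
#' | LR    | multinomial logistic regression | nnet |
#' | ET    | extremely randomized trees      | ranger |
#' | RF    | random forest                   | ranger |
#' | LDA   | linear discriminant analysis    | MASS |
#' | LGBM  | leaf-wise (loss-guided) histogram gradient boosting | xgboost |
#' | GNB   | Gaussian naive Bayes            | e1071 |
#' | QDA   | quadratic discriminant analysis | MASS |
#' | Ridge | ridge regression on class indicators | built in |
#' | GB    | depth-wise gradient boosting    | xgboost |
#' | DT    | decision tree                   | rpart |
#' | Ada   | SAMME AdaBoost over stumps      | built in (rpart stumps) |
#'
#' The shipped SVM defaults are `cost = 1.09`, `gamma = 1/72`, with no
#' feature scaling (tangent-space features are already whitened relative
#' to the reference mean).
#'
#' @param name One of the 13 family names above.
#' @param ... Hyperparameter overrides (family-specific, e.g. `cost`,
#'   `gamma` for SVM; `k` for kNN; `num_trees` for RF/ET; `nrounds`,
#'   `eta`, `max_depth` for GB; `lambda` for Ridge; `n_stumps` for Ada).
#' @return A `classifier_spec` list with fields `name`, `params`.
#' @examples
#' classifier_spec("SVM")
#' classifier_spec("kNN", k = 7)
#' @export
classifier_spec <- function(name, ...) {
  name <- match.arg(name, classifier_families())
  defaults <- switch(name,
    SVM   = list(cost = 1.09, gamma = 1 / 72),
    kNN   = list(k = 5),
    LR    = list(decay = 0, maxit = 200),
    ET    = list(num_trees = 200),
    RF    = list(num_trees = 200),
    LDA   = list(),
    LGBM  = list(nrounds = 100, eta = 0.1, max_leaves = 31),
    GNB   = list(),
    QDA   = list(),
    Ridge = list(lambda = 1),
    GB    = list(nrounds = 100, eta = 0.1, max_depth = 3),
    DT    = list(),
    Ada   = list(n_stumps = 50)
  )
  structure(list(name = name, params = utils::modifyList(defaults, list(...))),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
classifier_families <- function() {
  c("SVM", "kNN", "LR", "ET", "RF", "LDA", "LGBM", "GNB", "QDA",
    "Ridge", "GB", "DT", "Ada")
}

#' @rdname classifier_spec
#' @export
default_classifier_specs <- function() {
  lapply(classifier_families(), classifier_spec)
}

#' @export
print.classifier_spec <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), vapply(x$params, format, ""), sep = "=", collapse = ", ")
  } else "family defaults"
  cat(sprintf("<classifier_spec> %s (%s)\n", x$name, ps))
  invisible(x)
}

# ---- engine dispatch -------------------------------------------------------

# fit one classifier family on a features matrix X (n x d) and labels y.
# levels fixes the label universe so predictions can never leave it.
fit_model <- function(spec, X, y, levels, seed) {
  y <- factor(y, levels = levels)
  p <- spec$params
  set.seed(seed)
  fit <- switch(spec$name,
    SVM = e1071::svm(X, y, kernel = "radial", cost = p$cost, gamma = p$gamma,
                     scale = FALSE),
    kNN = list(X = X, y = y, k = p$k),
    LR = {
      df <- data.frame(.y = y, X)
      nnet::multinom(.y ~ ., df, trace = FALSE, maxit = p$maxit, decay = p$decay,
                     MaxNWts = (ncol(X) + 2L) * nlevels(y) + 10L)
    },
    ET = ranger::ranger(x = X, y = y, num.trees = p$num_trees,
                        splitrule = "extratrees", num.random.splits = 1,
                        replace = FALSE, sample.fraction = 1,
                        seed = seed, num.threads = 1),
    RF = ranger::ranger(x = X, y = y, num.trees = p$num_trees,
                        seed = seed, num.threads = 1),
    LDA = MASS::lda(X, grouping = y),
    LGBM = fit_xgb(X, y, nrounds = p$nrounds, eta = p$eta, seed = seed,
                   extra = list(tree_method = "hist", grow_policy = "lossguide",
                                max_depth = 0, max_leaves = p$max_leaves)),
    GNB = e1071::naiveBayes(X, y),
    QDA = MASS::qda(X, grouping = y),
    Ridge = fit_ridge(X, y, lambda = p$lambda),
    GB = fit_xgb(X, y, nrounds = p$nrounds, eta = p$eta, seed = seed,
                 extra = list(max_depth = p$max_depth)),
    DT = {
      df <- data.frame(.y = y, X)
      rpart::rpart(.y ~ ., df, method = "class")
    },
    Ada = fit_samme(X, y, n_stumps = p$n_stumps)
  )
  structure(list(name = spec$name, fit = fit, levels = levels),
            class = "emg_classifier")
}

predict_model <- function(model, X) {
  fit <- model$fit
  out <- switch(model$name,
    SVM = as.character(predict(fit, X)),
    kNN = as.character(class::knn(fit$X, X, fit$y, k = fit$k)),
    LR = as.character(predict(fit, data.frame(X), type = "class")),
    ET = ,
    RF = as.character(predict(fit, data = as.data.frame(X),
                              num.threads = 1)$predictions),
    LDA = ,
    QDA = as.character(predict(fit, X)$class),
    LGBM = ,
    GB = predict_xgb(fit, X, model$levels),
    GNB = as.character(predict(fit, X)),
    Ridge = predict_ridge(fit, X),
    DT = as.character(predict(fit, data.frame(X), type = "class")),
    Ada = predict_samme(fit, X)
  )
  factor(out, levels = model$levels)
}

# xgboost multiclass wrapper (num_class from the label universe)
fit_xgb <- function(X, y, nrounds, eta, seed, extra = list()) {
  k <- nlevels(y)
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
  params <- c(list(objective = "multi:softmax", num_class = k, eta = eta,
                   nthread = 1, seed = seed), extra)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

predict_xgb <- function(fit, X, levels) {
  idx <- predict(fit, xgboost::xgb.DMatrix(X))
  levels[as.integer(idx) + 1L]
}

# ridge regression on one-hot class indicators, argmax decision rule;
# intercept left unpenalized
fit_ridge <- function(X, y, lambda) {
  Y <- diag(nlevels(y))[as.integer(y), , drop = FALSE]
  Xc <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, ncol(X))))
  W <- solve(crossprod(Xc) + pen, crossprod(Xc, Y))
  list(W = W, levels = levels(y))
}

predict_ridge <- function(fit, X) {
  scores <- cbind(1, X) %*% fit$W
  fit$levels[max.col(scores, ties.method = "first")]
}

# multiclass AdaBoost (SAMME) with depth-1 rpart stumps
fit_samme <- function(X, y, n_stumps) {
  n <- nrow(X); k <- nlevels(y)
  df <- data.frame(.y = y, X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_stumps)) {
    st <- rpart::rpart(.y ~ ., df, weights = w, method = "class",
                       control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                      minsplit = 2, xval = 0))
    pred <- predict(st, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / k) break                 # worse than chance: stop
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[m]] <- st; alphas[m] <- alpha
    if (err < 1e-10) break                      # perfect stump
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_samme <- function(fit, X) {
  df <- data.frame(X)
  k <- length(fit$levels)
  votes <- matrix(0, nrow(X), k, dimnames = list(NULL, fit$levels))
  for (m in seq_along(fit$stumps)) {
    pred <- as.character(predict(fit$stumps[[m]], df, type = "class"))
    votes[cbind(seq_len(nrow(X)), match(pred, fit$levels))] <-
      votes[cbind(seq_len(nrow(X)), match(pred, fit$levels))] + fit$alphas[m]
  }
  fit$levels[max.col(votes, ties.method = "first")]
}

# ---- pipeline --------------------------------------------------------------

#' Fit the full covariance/tangent-space gesture pipeline
#'
#' From labelled windows: computes per-window spatial covariance matrices,
#' the Frechet mean of the *training* covariances (the tangent-space
#' reference), maps training windows to tangent features, and fits the
#' requested classifier. The returned pipeline carries everything needed
#' to classify new windows: the reference matrix, the fitted model, the
#' label vocabulary and the segmentation metadata.
#'
#' @param train An `emg_segments` with at least 2 classes present.
#' @param spec A [classifier_spec] (default: the shipped SVM).
#' @param seed Integer seed for any stochastic fitting step; the fit is
#'   deterministic given the seed.
#' @param shrinkage Diagonal loading for [spatial_covariance()].
#' @return An `emg_pipeline` object.
#' @examples
#' sess <- generate_recording(synth_config(trials = 1, gestures = c("I", "F", "S"),
#'                                         powerline_amp = 0))
#' seg <- segment_windows(sess$recording, sess$cues, overlap = 0.5)
#' pipe <- fit_pipeline(seg)
#' table(predict(pipe, seg) == seg$label)
#' @export
fit_pipeline <- function(train, spec = classifier_spec("SVM"), seed = 1,
                         shrinkage = 1e-8) {
  stopifnot(inherits(train, "emg_segments"))
  if (length(train) == 0) stop_emg("empty_input", "no training windows")
  if (length(unique(train$label)) < 2) {
    stop_emg("single_class", "training set must contain >= 2 classes")
  }
  covs <- lapply(train$windows, spatial_covariance, shrinkage = shrinkage)
  reference <- frechet_mean(covs)
  feats <- tangent_map(covs, reference)
  levels <- train$label_set
  model <- fit_model(spec, unclass(feats), train$label, levels, seed)
  structure(
    list(reference = reference, model = model, spec = spec,
         label_set = levels, seed = seed, shrinkage = shrinkage,
         n_channels = nrow(reference),
         window_samples = train$window_samples,
         hop_samples = train$hop_samples, rate = train$rate,
         n_train = length(train)),
    class = "emg_pipeline"
  )
}

#' @export
print.emg_pipeline <- function(x, ...) {
  cat(sprintf("<emg_pipeline> %s on %d-channel tangent features (dim %d), %d training windows\n",
              x$spec$name, x$n_channels, x$n_channels * (x$n_channels + 1) / 2,
              x$n_train))
  cat("  labels:", paste(x$label_set, collapse = ", "), "\n")
  invisible(x)
}

#' Classify EMG windows with a fitted pipeline
#'
#' @param object An `emg_pipeline` from [fit_pipeline()].
#' @param segments An `emg_segments` (channel count must match the
#'   pipeline) or a list of channels x samples window matrices.
#' @param ... Unused.
#' @return Character vector: one predicted label per window, drawn from
#'   the pipeline's label set. A pure function of pipeline and input.
#' @export
predict.emg_pipeline <- function(object, segments, ...) {
  windows <- if (inherits(segments, "emg_segments")) segments$windows else segments
  if (length(windows) == 0) return(character(0))
  if (nrow(windows[[1]]) != object$n_channels) {
    stop_emg("dim_mismatch", "segment channel count (", nrow(windows[[1]]),
             ") does not match pipeline (", object$n_channels, ")")
  }
  covs <- lapply(windows, spatial_covariance, shrinkage = object$shrinkage)
  feats <- tangent_map(covs, object$reference)
  as.character(predict_model(object$model, unclass(feats)))
}

# ---- reports ---------------------------------------------------------------

# build a classification report from aligned true/predicted labels
classification_report <- function(truth, pred, levels, per_fold_accuracies,
                                  fold_info = NULL) {
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  confusion <- table(true = truth, predicted = pred)
  stopifnot(all(rowSums(confusion) == table(truth)))
  acc <- sum(diag(confusion)) / sum(confusion)
  colsum <- colSums(confusion)
  precision <- ifelse(colsum > 0, diag(confusion) / colsum, NA_real_)
  names(precision) <- levels
  structure(
    list(confusion = confusion, accuracy = acc,
         per_class_precision = precision,
         per_fold_accuracies = per_fold_accuracies,
         mean_accuracy = mean(per_fold_accuracies),
         sd_accuracy = stats::sd(per_fold_accuracies),
         folds = fold_info),
    class = "emg_report"
  )
}

#' @export
print.emg_report <- function(x, ...) {
  cat(sprintf("<emg_report> overall accuracy %.4f; per-fold %.4f +/- %.4f (%d folds)\n",
              x$accuracy, x$mean_accuracy,
              if (is.na(x$sd_accuracy)) 0 else x$sd_accuracy,
              length(x$per_fold_accuracies)))
  print(x$confusion)
  invisible(x)
}

#' Trial-wise cross-validation of the gesture pipeline
#'
#' Reproduces the two evaluation protocols used for short-calibration
#' gesture decoding:
#' \describe{
#'   \item{`leave_one_trial_out`}{each trial is held out once as the test
#'     set; the tangent-space reference (Frechet mean) *and* the
#'     classifier are refit per fold from the remaining trials only, so no
#'     test information leaks into fitting.}
#'   \item{`train_first_test_rest`}{the pipeline is fit once on trial 0
#'     and each remaining trial is scored separately (the long-term,
#'     train-once protocol: 11 trials give 10 test accuracies).}
#' }
#' Accuracy is counted per window by default; `score = "cue_vote"`
#' aggregates windows by majority vote within each cue before scoring.
#'
#' @param segments An `emg_segments` spanning >= 2 trials.
#' @param spec A [classifier_spec].
#' @param protocol `"leave_one_trial_out"` or `"train_first_test_rest"`.
#' @param seed Integer; fold f uses `seed + f` for its fit.
#' @param shrinkage Diagonal loading for the covariance estimates.
#' @param score `"window"` (default) or `"cue_vote"`.
#' @param keep_folds Keep per-fold reference matrices and fitted models
#'   (for leakage diagnostics); default `FALSE`.
#' @return An `emg_report`: aggregated confusion matrix (rows = true),
#'   overall `accuracy` (= trace/total), `per_class_precision`,
#'   `per_fold_accuracies` and their mean/SD.
#' @examples
#' sess <- generate_recording(synth_config(trials = 2, gestures = c("I", "F", "S"),
#'                                         powerline_amp = 0))
#' seg <- segment_windows(sess$recording, sess$cues, overlap = 0.5)
#' cross_validate_trials(seg)
#' @export
cross_validate_trials <- function(segments, spec = classifier_spec("SVM"),
                                  protocol = c("leave_one_trial_out",
                                               "train_first_test_rest"),
                                  seed = 1, shrinkage = 1e-8,
                                  score = c("window", "cue_vote"),
                                  keep_folds = FALSE) {
  protocol <- match.arg(protocol)
  score <- match.arg(score)
  stopifnot(inherits(segments, "emg_segments"))
  trials <- sort(unique(segments$trial))
  if (length(trials) < 2) {
    stop_emg("too_few_trials", "protocol needs >= 2 trials, got ", length(trials))
  }
  folds <- if (protocol == "leave_one_trial_out") {
    lapply(trials, function(t) list(train = trials[trials != t], test = t))
  } else {
    lapply(trials[-1], function(t) list(train = trials[1], test = t))
  }

  covs <- lapply(segments$windows, spatial_covariance, shrinkage = shrinkage)
  levels <- segments$label_set

  truth_all <- character(0); pred_all <- character(0)
  fold_acc <- numeric(length(folds)); fold_detail <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr_idx <- which(segments$trial %in% folds[[f]]$train)
    te_idx <- which(segments$trial %in% folds[[f]]$test)
    reference <- frechet_mean(covs[tr_idx])
    ftr <- unclass(tangent_map(covs[tr_idx], reference))
    fte <- unclass(tangent_map(covs[te_idx], reference))
    model <- fit_model(spec, ftr, segments$label[tr_idx], levels, seed + f)
    pred <- as.character(predict_model(model, fte))
    truth <- segments$label[te_idx]
    if (score == "cue_vote") {
      voted <- vote_by_cue(pred, truth, segments$cue_index[te_idx])
      pred <- voted$pred; truth <- voted$truth
    }
    fold_acc[f] <- mean(pred == truth)
    truth_all <- c(truth_all, truth); pred_all <- c(pred_all, pred)
    fold_detail[[f]] <- list(test_trial = folds[[f]]$test,
                             reference = if (keep_folds) reference,
                             model = if (keep_folds) model,
                             n_test = length(te_idx))
  }
  rpt <- classification_report(truth_all, pred_all, levels, fold_acc, fold_detail)
  rpt$protocol <- protocol
  rpt$spec <- spec
  rpt$seed <- seed
  rpt
}

vote_by_cue <- function(pred, truth, cue) {
  cues <- unique(cue)
  list(
    pred = vapply(cues, function(ci) {
      tab <- table(pred[cue == ci])
      names(tab)[which.max(tab)]
    }, character(1)),
    truth = vapply(cues, function(ci) truth[cue == ci][1], character(1))
  )
}

#' Grid search for SVM hyperparameters
#'
#' Exhaustive search over a cost x gamma grid with stratified k-fold inner
#' cross-validation on tangent features. Ties are broken toward the
#' smallest cost, then the smallest gamma.
#'
#' @param features A `tangent_features` matrix (or plain numeric matrix).
#' @param labels Labels aligned with rows of `features`.
#' @param grid Named list with numeric vectors `cost` and `gamma`
#'   (defaults: cost `2^(-5:5)`, gamma `2^(-10:2)`).
#' @param folds Number of stratified folds (default 5); must not exceed
#'   the smallest class count.
#' @param seed Integer seed controlling the fold assignment.
#' @return A list: `best` (`cost`, `gamma`, `accuracy`) and `table`, a
#'   tibble of all grid points with mean inner-CV accuracy.
#' @export
grid_search_svm <- function(features, labels,
                            grid = list(cost = 2^(-5:5), gamma = 2^(-10:2)),
                            folds = 5, seed = 1) {
  X <- unclass(features)
  y <- as.character(labels)
  if (length(grid$cost) == 0 || length(grid$gamma) == 0) {
    stop_emg("empty_grid", "grid must contain cost and gamma candidates")
  }
  cls_counts <- table(y)
  if (folds > min(cls_counts)) {
    stop_emg("too_many_folds", "folds (", folds, ") exceed smallest class count (",
             min(cls_counts), ")")
  }
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in names(cls_counts)) {          # stratified assignment
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  levels <- unique(y)
  pts <- expand.grid(cost = grid$cost, gamma = grid$gamma)
  acc <- vapply(seq_len(nrow(pts)), function(i) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f; te <- !tr
      m <- fit_model(classifier_spec("SVM", cost = pts$cost[i], gamma = pts$gamma[i]),
                     X[tr, , drop = FALSE], y[tr], levels, seed)
      mean(as.character(predict_model(m, X[te, , drop = FALSE])) == y[te])
    }, numeric(1)))
  }, numeric(1))
  tab <- tibble::tibble(cost = pts$cost, gamma = pts$gamma, accuracy = acc) |>
    dplyr::arrange(dplyr::desc(.data$accuracy), .data$cost, .data$gamma)
  list(best = as.list(tab[1, ]), table = tab)
}

#' Compare classifier families on identical folds and features
#'
#' Runs every requested classifier family through the same trial-wise
#' cross-validation: the fold split, the per-fold Frechet mean reference
#' and the per-fold tangent features are computed once and shared, so the
#' comparison isolates the classifier. A family whose fit or prediction
#' fails is recorded as `missing` with the error message, never silently
#' dropped.
#'
#' @inheritParams cross_validate_trials
#' @param specs List of [classifier_spec]s (default: all 13 families).
#' @return A `gesture_comparison` tibble, one row per classifier, sorted
#'   by descending mean accuracy: `classifier`, `mean_accuracy`,
#'   `sd_accuracy`, `n_folds`, `status`.
#' @export
compare_classifiers <- function(segments, specs = default_classifier_specs(),
                                protocol = c("leave_one_trial_out",
                                             "train_first_test_rest"),
                                seed = 1, shrinkage = 1e-8) {
  protocol <- match.arg(protocol)
  if (length(specs) < 2) stop_emg("too_few_specs", "need >= 2 classifier specs")
  stopifnot(inherits(segments, "emg_segments"))
  trials <- sort(unique(segments$trial))
  if (length(trials) < 2) stop_emg("too_few_trials", "need >= 2 trials")
  folds <- if (protocol == "leave_one_trial_out") {
    lapply(trials, function(t) list(train = trials[trials != t], test = t))
  } else {
    lapply(trials[-1], function(t) list(train = trials[1], test = t))
  }
  covs <- lapply(segments$windows, spatial_covariance, shrinkage = shrinkage)
  levels <- segments$label_set

  # shared per-fold features: compute once, reuse for every classifier
  shared <- lapply(folds, function(fold) {
    tr_idx <- which(segments$trial %in% fold$train)
    te_idx <- which(segments$trial %in% fold$test)
    reference <- frechet_mean(covs[tr_idx])
    list(ftr = unclass(tangent_map(covs[tr_idx], reference)),
         fte = unclass(tangent_map(covs[te_idx], reference)),
         ytr = segments$label[tr_idx], yte = segments$label[te_idx])
  })

  rows <- purrr::map(specs, function(spec) {
    res <- tryCatch({
      acc <- vapply(seq_along(shared), function(f) {
        s <- shared[[f]]
        m <- fit_model(spec, s$ftr, s$ytr, levels, seed + f)
        mean(as.character(predict_model(m, s$fte)) == s$yte)
      }, numeric(1))
      tibble::tibble(classifier = spec$name, mean_accuracy = mean(acc),
                     sd_accuracy = stats::sd(acc), n_folds = length(acc),
                     status = "ok")
    }, error = function(e) {
      tibble::tibble(classifier = spec$name, mean_accuracy = NA_real_,
                     sd_accuracy = NA_real_, n_folds = length(shared),
                     status = paste0("missing: ", conditionMessage(e)))
    })
    res
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$mean_accuracy))
  class(out) <- c("gesture_comparison", class(out))
  attr(out, "protocol") <- protocol
  attr(out, "seed") <- seed
  out
}

#' Chance-level (majority/dummy) baseline accuracy
#'
#' Accuracy of always predicting the most frequent training label —
#' `1 / K` on a balanced K-class set. Used as the floor in classifier
#' comparisons.
#'
#' @param labels Label vector.
#' @return Fraction in `[0, 1]`.
#' @export
dummy_accuracy <- function(labels) {
  max(table(labels)) / length(labels)
}
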