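# plain repeated k-fold CV on a fixed feature matrix to pick (gamma, cost);
# used when fitting the final online models (no outer loop needed there)
select_hyperparams <- function(x, y, costs, gammas, k = 10, repeats = 10,
                               seed = 1, eps = 1e-3, max_iter = 20000L) {
  n <- length(y)
  lab <- factor(y)
  acc <- matrix(0, length(gammas), length(costs))
  folds <- with_seed(seed, replicate(repeats,
    stratified_folds(lab, min(k, min(table(lab)))), simplify = FALSE))
  D <- sq_dist(x)
  for (g in seq_along(gammas)) {
    K <- exp(-gammas[g] * D)
    for (cc in seq_along(costs)) {
      hit <- 0L; tot <- 0L
      for (f in folds) {
        for (fold in seq_len(max(f))) {
          tr <- which(f != fold); te <- which(f == fold)
          fit <- smo_fit_cpp(K, tr - 1L, y, costs[cc], eps, max_iter)
          sc <- smo_decision_cpp(K, tr - 1L, te - 1L, fit$alpha, y[tr], fit$b)
          hit <- hit + sum(sign(sc) * y[te] > 0 | (sc == 0 & y[te] > 0))
          tot <- tot + length(te)
        }
      }
      acc[g, cc] <- hit / tot
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)[1, ]
  list(gamma = gammas[best[1]], cost = costs[best[2]], cv_accuracy = max(acc))
}

fit_rbf_svm <- function(x, y, cost, gamma, eps = 1e-3, max_iter = 20000L) {
  K <- rbf_kernel(x, gamma = gamma)
  fit <- smo_fit_cpp(K, seq_len(nrow(x)) - 1L, y, cost, eps, max_iter)
  list(x = x, y = y, alpha = fit$alpha, b = fit$b, cost = cost, gamma = gamma,
       obj = fit$obj)
}

svm_decision <- function(model, newx) {
  K <- rbf_kernel(newx, model$x, model$gamma)
  as.vector(K %*% (model$alpha * model$y)) + model$b
}

#' Train the online decoder (onset detector + class decoder)
#'
#' Builds the two-part online decoder used for closed-loop prosthesis control.
#' The class decoder is an RBF-kernel SVM fit on all trials at the peak-
#' accuracy window of the offline task (taken from `cv_result`, or recomputed);
#' its hyperparameters are chosen by repeated cross-validation on the full
#' training set. The onset detector is a move-vs-rest SVM whose positive
#' examples are the post-cue window features and whose negatives are windows
#' tiled over the rest baseline, with a scalar decision threshold that
#' [calibrate_onset_threshold()] can raise post hoc.
#'
#' The label policy identifies the three decoder conditions: `true_labels`
#' (phantom decoder), `permuted_labels` (random decoder: class labels
#' uniformly shuffled before training), `other_effector` (real-hand decoder:
#' the class model is trained on the intact-hand session's features supplied
#' via `intact_features`).
#'
#' @param features z-scored offline `feature_set` of the phantom-hand task.
#' @param recording the session the features came from (supplies the baseline
#'   negatives and the z-scoring statistics reused online).
#' @param policy `"true_labels"`, `"permuted_labels"` or `"other_effector"`.
#' @param intact_features intact-hand `feature_set`, required under
#'   `other_effector`.
#' @param cv_result optional [nested_cv_accuracy()] result for the class
#'   features; recomputed (same seed) when missing.
#' @param onset_lock whether onset-detector positives are locked to the
#'   execution cue (default) or to the instruction; the instruction variant
#'   shifts positives to the instruction-locked windows.
#' @param costs,gammas hyperparameter grid for the class model.
#' @param seed integer seed.
#' @return object of class `online_decoder`.
#' @export
train_online_decoder <- function(features, recording,
                                 policy = c("true_labels", "permuted_labels",
                                            "other_effector"),
                                 intact_features = NULL, cv_result = NULL,
                                 onset_lock = c("execution", "instruction"),
                                 costs = c(0.1, 1, 10), gammas = NULL,
                                 seed = 1) {
  policy <- match.arg(policy)
  onset_lock <- match.arg(onset_lock)
  stopifnot(inherits(features, "feature_set"),
            inherits(recording, "session_recording"))
  seeds <- derive_seeds(seed, 4L)

  class_feats <- switch(policy,
    true_labels = features,
    permuted_labels = permute_labels(features, seed = seeds[1]),
    other_effector = {
      if (is.null(intact_features))
        stop("policy 'other_effector' requires `intact_features`", call. = FALSE)
      intact_features
    })

  n_chan <- dim(class_feats$features)[3]
  if (is.null(gammas)) gammas <- c(0.1, 1, 10) / n_chan
  if (is.null(cv_result))
    cv_result <- nested_cv_accuracy(class_feats, seed = seeds[2],
                                    costs = costs, gammas = gammas)
  w <- match(cv_result$selected_window, class_feats$window_offsets)
  xw <- matrix(class_feats$features[, w, ], ncol = n_chan)
  yw <- ifelse(class_feats$labels == levels(class_feats$labels)[1], 1, -1)
  hp <- select_hyperparams(xw, yw, costs, gammas, seed = seeds[3])
  class_model <- fit_rbf_svm(xw, yw, hp$cost, hp$gamma)
  class_model$levels <- levels(class_feats$labels)

  # onset detector: post-cue windows vs rest-baseline windows
  lock_shift <- if (onset_lock == "instruction") -3000 else 0
  onset_feats <- session_features(recording,
                                  range = c(-500 + lock_shift, 1000 + lock_shift),
                                  window = features$window, step = features$step)
  # positives: windows covering at least half of the 0-500 ms movement burst
  starts <- onset_feats$window_offsets - lock_shift
  overlap <- (pmin(starts + features$window, 500) - pmax(starts, 0)) /
    features$window
  post <- overlap >= 0.5
  pos <- matrix(onset_feats$features[, post, ], ncol = n_chan)

  bs <- features$baseline_stats %||% baseline_stats(recording, features$window,
                                                    features$step)
  rate <- recording$sampling_rate
  span <- recording$schedule$baseline_span
  wl <- round(features$window / 1000 * rate)
  sl <- round(features$step / 1000 * rate)
  bl <- t(recording$signal[recording$selected_channels,
                           (floor(span[1] / 1000 * rate) + 1):
                             floor(span[2] / 1000 * rate), drop = FALSE])
  neg_raw <- window_means(bl, seq(1L, nrow(bl) - wl + 1L, by = sl), wl)
  neg <- sweep(sweep(neg_raw, 2, bs$mean), 2, bs$sd, "/")
  n_keep <- min(nrow(pos), nrow(neg))
  pick <- with_seed(seeds[4], list(p = sample.int(nrow(pos), n_keep),
                                   n = sample.int(nrow(neg), n_keep)))
  xo <- rbind(pos[pick$p, , drop = FALSE], neg[pick$n, , drop = FALSE])
  yo <- rep(c(1, -1), each = n_keep)
  onset_model <- fit_rbf_svm(xo, yo, cost = 10, gamma = 1 / n_chan)

  structure(list(class_model = class_model, onset_model = onset_model,
                 onset_threshold = 0,
                 selected_window = cv_result$selected_window,
                 window = features$window, step = features$step,
                 baseline_stats = bs, policy = policy, onset_lock = onset_lock,
                 cv_result = cv_result, seed = seed),
            class = "online_decoder")
}

#' Decode z-scored window features with an online decoder
#'
#' @param object an `online_decoder`.
#' @param newdata matrix (windows x channels) of z-scored window means.
#' @param what `"class"` for grasp/open labels, `"onset"` for the onset
#'   detector's decision scores, `"both"` for a data.frame of scores, detected
#'   onsets (score >= threshold) and decoded classes.
#' @param ... unused.
#' @return see `what`.
#' @export
predict.online_decoder <- function(object, newdata,
                                   what = c("both", "class", "onset"), ...) {
  what <- match.arg(what)
  newdata <- as.matrix(newdata)
  if (what %in% c("onset", "both"))
    onset_score <- svm_decision(object$onset_model, newdata)
  if (what == "onset") return(onset_score)
  cls_score <- svm_decision(object$class_model, newdata)
  cls <- factor(ifelse(cls_score >= 0, object$class_model$levels[1],
                       object$class_model$levels[2]),
                levels = object$class_model$levels)
  if (what == "class") return(cls)
  data.frame(onset_score = onset_score,
             onset = onset_score >= object$onset_threshold,
             class = cls, class_score = cls_score)
}

#' Calibrate the onset threshold against a resting-state stream
#'
#' Slides the decoder's analysis window over a rest recording, scores every
#' window with the onset detector, and returns the smallest threshold that
#' yields zero detections on that stream (detection rule: score >= threshold),
#' i.e. the maximum observed rest score plus a safety margin. This mirrors the
#' experimenter raising the threshold until rest no longer triggers the
#' prosthesis.
#'
#' @param decoder an `online_decoder`.
#' @param rest a rest `session_recording` (>= 10 s) or a channels x samples
#'   matrix at the decoder's sampling rate.
#' @param step_ms stride of the scoring windows.
#' @param margin safety margin added above the maximum rest score.
#' @param sampling_rate required when `rest` is a bare matrix.
#' @return the calibrated threshold (numeric); also returned invisibly inside
#'   the updated decoder via attribute `decoder`.
#' @export
calibrate_onset_threshold <- function(decoder, rest, step_ms = 100,
                                      margin = 0.01, sampling_rate = NULL) {
  stopifnot(inherits(decoder, "online_decoder"))
  if (inherits(rest, "session_recording")) {
    sampling_rate <- rest$sampling_rate
    x <- rest$signal[rest$selected_channels, , drop = FALSE]
  } else {
    x <- as.matrix(rest)
    if (is.null(sampling_rate))
      stop("`sampling_rate` needed for a bare matrix", call. = FALSE)
  }
  if (ncol(x) / sampling_rate < 10)
    stop("rest stream must be at least 10 s long", call. = FALSE)
  wl <- round(decoder$window / 1000 * sampling_rate)
  sl <- round(step_ms / 1000 * sampling_rate)
  wm <- window_means(t(x), seq(1L, ncol(x) - wl + 1L, by = sl), wl)
  z <- sweep(sweep(wm, 2, decoder$baseline_stats$mean), 2,
             decoder$baseline_stats$sd, "/")
  scores <- svm_decision(decoder$onset_model, z)
  thr <- max(scores) + margin
  dec <- decoder
  dec$onset_threshold <- thr
  attr(thr, "decoder") <- dec
  attr(thr, "rest_scores") <- scores
  thr
}

#' @export
print.online_decoder <- function(x, ...) {
  cat(sprintf(
    "<online_decoder> policy '%s', class window %+d ms, onset threshold %.3f\n",
    x$policy, as.integer(x$selected_window), x$onset_threshold))
  invisible(x)
}
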