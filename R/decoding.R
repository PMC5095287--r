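# squared-Euclidean distance matrix between rows
sq_dist <- function(x, y = x) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

rbf_kernel <- function(x, y = x, gamma) exp(-gamma * sq_dist(x, y))

# stratified fold assignment: per class, shuffle and deal folds cyclically
stratified_folds <- function(labels, k) {
  out <- integer(length(labels))
  for (cl in levels(labels)) {
    rows <- which(labels == cl)
    out[rows[sample.int(length(rows))]] <- rep_len(seq_len(k), length(rows))
  }
  out
}

#' Window-resolved nested cross-validated classification accuracy
#'
#' Two-class radial-basis-kernel SVM decoding with nested cross-validation.
#' The outer `k_outer`-fold loop estimates accuracy; within each outer
#' training set, `inner_repeats` repetitions of `k_inner`-fold CV score every
#' (cost, kernel width) combination at every time window, and the combination
#' with the highest average inner accuracy is selected before the outer-fold
#' model is refit and applied to the held-out outer fold. The classification
#' accuracy pools every outer fold's test predictions at that fold's selected
#' (window, hyperparameter) combination, so hyperparameters and windows are
#' never chosen with any influence from the trials they are evaluated on and
#' the estimate is unbiased at chance level for uninformative data.
#' `accuracy_by_window` (outer predictions pooled per window, each window
#' using its own inner-selected hyperparameters) and its maximum
#' `max_window_accuracy` are kept as the window-resolved diagnostic;
#' `selected_window` is the window chosen by most outer folds (earliest on
#' ties).
#'
#' @param features a z-scored `feature_set` (see [session_features()]).
#' @param k_outer,k_inner outer/inner fold counts.
#' @param inner_repeats repetitions of the inner CV.
#' @param costs SVM regularization grid.
#' @param gammas RBF width grid; default `c(0.1, 1, 10) / n_channels`.
#' @param seed integer seed for the fold assignments.
#' @param eps,max_iter SMO stopping tolerance and iteration cap.
#'
#' @return object of class `decoding_result`: `classification_accuracy`,
#'   `selected_window`, `accuracy_by_window` (named by window offset, ms),
#'   `max_window_accuracy`, `inner_cv_table` ((gamma x cost) x window mean
#'   inner accuracies), `inner_by_fold` (the same per outer fold; the
#'   no-leakage audit trail), `fold_window` (window picked by each outer
#'   fold), `best_combo`, `grid` and fold bookkeeping.
#' @export
nested_cv_accuracy <- function(features, k_outer = 10, k_inner = 10,
                               inner_repeats = 10, costs = c(0.1, 1, 10),
                               gammas = NULL, seed = 1, eps = 1e-3,
                               max_iter = 20000L) {
  stopifnot(inherits(features, "feature_set"))
  k_outer <- assert_count(k_outer, "k_outer", min = 2L)
  labels <- droplevels(features$labels)
  if (nlevels(labels) < 2L)
    stop("decoding needs two classes; input has one", call. = FALSE)
  counts <- table(labels)
  if (any(counts < k_outer))
    stop(sprintf("each class needs >= k_outer = %d trials (have %s)",
                 k_outer, paste(counts, collapse = "/")), call. = FALSE)

  n <- length(labels)
  n_chan <- dim(features$features)[3]
  n_win <- dim(features$features)[2]
  offsets <- features$window_offsets
  if (is.null(gammas)) gammas <- c(0.1, 1, 10) / n_chan
  y <- ifelse(labels == levels(labels)[1], 1, -1)

  # kernels per (gamma, window), shared by all folds
  Ks <- vector("list", length(gammas) * n_win)
  for (w in seq_len(n_win)) {
    D <- sq_dist(matrix(features$features[, w, ], nrow = n))
    for (g in seq_along(gammas))
      Ks[[(g - 1L) * n_win + w]] <- exp(-gammas[g] * D)
  }

  n_combo <- length(gammas) * length(costs)
  do_inner <- n_combo > 1L || n_win > 1L
  assign <- with_seed(seed, {
    outer_assign <- stratified_folds(labels, k_outer)
    inner_assign <- lapply(seq_len(k_outer), function(k) {
      ia <- matrix(0L, n, max(1L, inner_repeats))
      if (do_inner) {
        tr <- which(outer_assign != k)
        ki <- min(k_inner, min(table(labels[tr])))
        for (r in seq_len(ncol(ia)))
          ia[tr, r] <- stratified_folds(droplevels(labels[tr]), ki)
      }
      ia
    })
    list(outer = outer_assign, inner = inner_assign)
  })

  res <- nested_cv_cpp(Ks, y, assign$outer, assign$inner, costs,
                       length(gammas), n_win, eps, as.integer(max_iter))

  acc <- colMeans(res$pred == y)
  names(acc) <- offsets
  combo_names <- as.vector(t(outer(seq_along(gammas), seq_along(costs),
    function(g, c) sprintf("gamma=%.4g,cost=%.4g", gammas[g], costs[c]))))
  inner_by_fold <- res$inner_by_fold
  dimnames(inner_by_fold) <- list(combo_names, offsets, NULL)
  inner_tab <- apply(inner_by_fold, c(1, 2), mean)

  # each outer fold contributes predictions at its inner-CV-selected window
  fold_window <- vapply(seq_len(k_outer), function(k) {
    per_w <- apply(inner_by_fold[, , k, drop = FALSE], 2, max)
    if (all(is.na(per_w))) 1L else which.max(per_w)  # earliest wins ties
  }, integer(1))
  nested_pred <- integer(n)
  for (k in seq_len(k_outer)) {
    rows <- assign$outer == k
    nested_pred[rows] <- res$pred[rows, fold_window[k]]
  }
  win_tab <- tabulate(fold_window, n_win)
  sel_w <- which.max(win_tab)  # majority window, earliest on ties

  structure(list(classification_accuracy = mean(nested_pred == y),
                 selected_window = offsets[sel_w],
                 accuracy_by_window = acc,
                 max_window_accuracy = unname(max(acc)),
                 fold_window = offsets[fold_window],
                 inner_cv_table = inner_tab,
                 inner_by_fold = inner_by_fold,
                 best_combo = res$best_combo,
                 grid = list(costs = costs, gammas = gammas),
                 outer_assign = assign$outer,
                 n_trials = n, seed = seed),
            class = "decoding_result")
}

#' Uniformly permute the class labels of a feature set
#'
#' The feature array is untouched; only the label vector is shuffled, so the
#' label multiset is preserved. Decoding permuted-label features estimates the
#' empirical chance level of the full pipeline.
#'
#' @param features a `feature_set`.
#' @param seed integer seed.
#' @return the `feature_set` with shuffled labels and `permuted = TRUE`.
#' @export
permute_labels <- function(features, seed = 1) {
  stopifnot(inherits(features, "feature_set"))
  if (length(features$labels) < 2L)
    stop("need at least 2 trials to permute", call. = FALSE)
  features$labels <- with_seed(seed,
    features$labels[sample.int(length(features$labels))])
  features$permuted <- TRUE
  features
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> accuracy %.3f at window %+d ms (n = %d trials)\n",
    x$classification_accuracy, as.integer(x$selected_window), x$n_trials))
  print(round(x$accuracy_by_window, 3))
  invisible(x)
}

#' @export
plot.decoding_result <- function(x, ...) {
  off <- as.numeric(names(x$accuracy_by_window))
  plot(off, x$accuracy_by_window, type = "b", pch = 16,
       xlab = "window start (ms, cue-locked)", ylab = "accuracy",
       ylim = c(0.3, 1), ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey")
  graphics::abline(v = x$selected_window, lty = 3)
  invisible(x)
}
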