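test_that("the SMO solver matches the reference libsvm implementation", {
  skip_if_not_installed("e1071")
  set.seed(42)
  for (rep in 1:15) {
    n <- sample(20:60, 1); p <- sample(2:8, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- sign(rnorm(n)); y[y == 0] <- 1
    if (length(unique(y)) < 2) next
    gam <- runif(1, 0.05, 1)
    C <- sample(c(0.1, 1, 10, 100), 1)
    K <- exp(-gam * as.matrix(dist(x))^2)
    f <- megbmi:::smo_fit_cpp(K, 0:(n - 1), y, C, 1e-5, 2e5)
    m <- e1071::svm(x, factor(y), kernel = "radial", gamma = gam, cost = C,
                    scale = FALSE)
    dv <- attr(predict(m, x, decision.values = TRUE), "decision.values")
    sgn <- if (colnames(dv) == "1/-1") 1 else -1
    mine <- megbmi:::smo_decision_cpp(K, 0:(n - 1), 0:(n - 1), f$alpha, y, f$b)
    expect_lt(max(abs(mine - sgn * as.vector(dv))), 5e-3)
    # dual constraints hold
    expect_true(all(f$alpha >= -1e-9 & f$alpha <= C + 1e-9))
    expect_lt(abs(sum(f$alpha * y)), 1e-8)
  }
})

test_that("permuting labels preserves the label multiset and the features", {
  f <- toy_features(n_per_class = 10, sep = 2, seed = 1)
  p <- permute_labels(f, seed = 3)
  expect_equal(as.integer(table(p$labels)), as.integer(table(f$labels)))
  expect_identical(p$features, f$features)
  expect_identical(permute_labels(f, seed = 3)$labels, p$labels)
  expect_false(identical(p$labels, f$labels))
  expect_error(permute_labels(toy_features(n_per_class = 0)), "2 trials")
})

test_that("nested CV rejects degenerate inputs", {
  f <- toy_features(n_per_class = 12)
  f1 <- f; f1$labels <- factor(rep("grasp", 24), levels = c("grasp", "open"))
  expect_error(nested_cv_accuracy(f1), "two classes")
  f2 <- toy_features(n_per_class = 4)
  expect_error(nested_cv_accuracy(f2, k_outer = 10), "k_outer")
})

test_that("a noiseless separable session is decoded perfectly", {
  hm <- mini_head_model(seed = 1)
  sched <- make_task_schedule(4, 3, seed = 2, sampling_rate = 200)
  # near-zero noise at a fixed burst amplitude: classes are point-separable
  rec <- simulate_session(hm, sched, d = 1, noise_sd = 1e-4, source_amp = 0.2,
                          seed = 3)
  f <- session_features(rec)
  r <- nested_cv_accuracy(f, k_outer = 5, k_inner = 5, inner_repeats = 2,
                          seed = 4)
  expect_equal(r$classification_accuracy, 1)
  # nearest-centroid oracle agrees that classes are point-separable
  x0 <- matrix(f$features[, match(0, f$window_offsets), ],
               nrow = length(f$labels))
  cen <- rbind(colMeans(x0[f$labels == "grasp", ]),
               colMeans(x0[f$labels == "open", ]))
  d2 <- sq_dist_r <- as.matrix(dist(rbind(x0, cen)))
  nc <- apply(d2[seq_len(nrow(x0)), nrow(x0) + 1:2], 1, which.min)
  expect_equal(nc, as.integer(f$labels), ignore_attr = TRUE)
})

test_that("the selected window matches the planted burst offset", {
  hm <- mini_head_model(seed = 5)
  sched <- make_task_schedule(5, 2, seed = 6, sampling_rate = 200)
  rec <- simulate_session(hm, sched, d = 1, noise_sd = 1, seed = 7)
  r <- nested_cv_accuracy(session_features(rec), k_outer = 5, k_inner = 5,
                          inner_repeats = 10, seed = 8)
  # burst occupies 0-500 ms; the 0 ms window covers it exactly, and its
  # 100-ms neighbours still cover 80% of it
  expect_true(abs(r$selected_window) <= 100)
})

test_that("accuracy rises monotonically with planted discriminability", {
  hm <- mini_head_model(seed = 9, n_sensors = 8, n_vertices = 6)
  mean_acc <- sapply(c(0, 0.5, 1, 2), function(d) {
    mean(sapply(1:20, function(i) {
      sched <- make_task_schedule(5, 4, seed = 1000 * d + i,
                                  sampling_rate = 200)
      rec <- simulate_session(hm, sched, d = d, noise_sd = 1,
                              seed = 2000 * d + i)
      nested_cv_accuracy(session_features(rec), k_outer = 5, k_inner = 4,
                         inner_repeats = 2, costs = c(1, 10),
                         seed = i)$classification_accuracy
    }))
  })
  expect_true(all(diff(mean_acc) > -0.02))  # non-decreasing up to MC noise
  expect_lt(mean_acc[1], 0.58)
  expect_gt(mean_acc[4], 0.8)
  expect_gt(mean_acc[4], mean_acc[1] + 0.2)
})

test_that("outer-fold test trials never influence inner-CV selection (poison audit)", {
  f <- toy_features(n_per_class = 15, n_win = 3, sep = 0.8, seed = 11)
  r_clean <- nested_cv_accuracy(f, k_outer = 5, k_inner = 5,
                                inner_repeats = 3, seed = 13)
  # poison the trials of outer fold 1 with a label-revealing feature
  poisoned <- f
  rows <- r_clean$outer_assign == 1
  poisoned$features[rows, , 2] <- ifelse(poisoned$labels[rows] == "grasp",
                                         100, -100)
  r_poison <- nested_cv_accuracy(poisoned, k_outer = 5, k_inner = 5,
                                 inner_repeats = 3, seed = 13)
  # fold 1's inner-CV table and selected combination are untouched
  expect_identical(r_poison$inner_by_fold[, , 1], r_clean$inner_by_fold[, , 1])
  expect_identical(r_poison$best_combo[1, ], r_clean$best_combo[1, ])
  expect_identical(r_poison$fold_window[1], r_clean$fold_window[1])
})

test_that("decoding results expose coherent bookkeeping", {
  f <- toy_features(n_per_class = 12, sep = 1.5, seed = 17)
  r <- nested_cv_accuracy(f, k_outer = 4, k_inner = 4, inner_repeats = 2,
                          seed = 19)
  expect_true(all(r$accuracy_by_window >= 0 & r$accuracy_by_window <= 1))
  expect_equal(r$max_window_accuracy, max(r$accuracy_by_window))
  expect_true(r$selected_window %in% f$window_offsets)
  expect_true(all(r$fold_window %in% f$window_offsets))
  expect_identical(
    nested_cv_accuracy(f, k_outer = 4, k_inner = 4, inner_repeats = 2,
                       seed = 19)$classification_accuracy,
    r$classification_accuracy)
})
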