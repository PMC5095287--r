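# wrap plain matrices as a feature_set for direct F-map input
as_features <- function(x, labels, offsets = 0) {
  structure(list(features = array(x, dim = c(nrow(x), 1, ncol(x))),
                 window_offsets = offsets, labels = labels, window = 500,
                 step = 100, sampling_rate = 1000,
                 channels = seq_len(ncol(x)), baseline_stats = NULL,
                 zscored = TRUE),
            class = "feature_set")
}

two_groups <- factor(rep(c("grasp", "open"), each = 3))

test_that("the F statistic reproduces the hand sums-of-squares value", {
  # class A = {0,1,2}, class B = {3,4,5}: SSB = 13.5 (MSB 13.5), SSW = 4
  # (MSW 1) -> F = 13.5
  fm <- vertex_f_map(as_features(matrix(c(0, 1, 2, 3, 4, 5), ncol = 1),
                                 two_groups))
  expect_equal(fm$f_values, 13.5)
  expect_equal(unname(fm$df), c(1L, 4L))
})

test_that("equal class means give F = 0", {
  x <- matrix(c(-1, 1, 0, -1, 1, 0), ncol = 1)
  fm <- vertex_f_map(as_features(x, two_groups))
  expect_equal(fm$f_values, 0)
})

test_that("for two classes F equals the squared pooled t statistic", {
  set.seed(21)
  for (i in 1:20) {
    x <- matrix(rnorm(24 * 3), 24, 3)
    lab <- factor(rep(c("grasp", "open"), each = 12))
    fm <- vertex_f_map(as_features(x, lab))
    for (v in 1:3) {
      tt <- t.test(x[lab == "grasp", v], x[lab == "open", v],
                   var.equal = TRUE)
      expect_equal(fm$f_values[v], unname(tt$statistic)^2, tolerance = 1e-10)
    }
  }
})

test_that("the vectorized F map matches the aov reference per vertex", {
  set.seed(22)
  x <- matrix(rnorm(30 * 5), 30, 5)
  lab <- factor(rep(c("grasp", "open"), 15))
  fm <- vertex_f_map(as_features(x, lab))
  for (v in 1:5) {
    ref <- summary(aov(x[, v] ~ lab))[[1]]$`F value`[1]
    expect_equal(fm$f_values[v], ref, tolerance = 1e-10)
  }
})

test_that("zero within-class variance is flagged, not silently NaN", {
  x <- cbind(c(1, 1, 1, 2, 2, 2), c(3, 3, 3, 3, 3, 3))
  fm <- vertex_f_map(as_features(x, two_groups))
  expect_identical(fm$f_values[1], Inf)
  expect_identical(fm$f_values[2], 0)
  expect_identical(fm$degenerate, c(TRUE, TRUE))
})

test_that("F-map input validation", {
  x <- matrix(rnorm(6), ncol = 1)
  expect_error(vertex_f_map(as_features(x, factor(rep("grasp", 6),
                                                  levels = c("grasp", "open")))),
               "2 classes")
  expect_error(vertex_f_map(as_features(x, two_groups), offset = 250),
               "not a feature window")
})

test_that("ROI selection returns the labelled sensorimotor vertices", {
  hm <- build_toy_head_model(8, 6, roi_fraction = 0.5, seed = 1)
  roi_c <- select_roi(hm, "contra")
  expect_true(all(hm$vertex_region[roi_c] == "sensorimotor"))
  expect_true(all(hm$vertex_hemi[roi_c] == "contra"))
  hm_all <- build_toy_head_model(8, 6, roi_fraction = 1, seed = 1)
  expect_length(select_roi(hm_all, "ipsi"), 6)
})

test_that("ROI decoding separates the active from the silent hemisphere", {
  params <- cohort_session_params(seed = 3)
  hm <- params$head_model
  diffs <- sapply(1:4, function(i) {
    sched <- make_task_schedule(5, 4, seed = 40 + i, sampling_rate = 100)
    rec <- simulate_session(hm, sched, d = 1.2, noise_sd = 1, seed = 50 + i)
    filt <- estimate_inverse_filter(rec, hm, inverse_config(tol = 1e-4))
    cf <- apply_filter_and_zscore(filt, rec, 0, 500)
    pr <- decode_profile("fast")
    acc_c <- roi_decoding_accuracy(cf, select_roi(hm, "contra"), pr,
                                   seed = i)$classification_accuracy
    acc_i <- roi_decoding_accuracy(cf, select_roi(hm, "ipsi"), pr,
                                   seed = i)$classification_accuracy
    c(acc_c, acc_i)
  })
  expect_gt(mean(diffs[1, ]), mean(diffs[2, ]) + 0.1)
  # silent hemisphere stays near chance
  expect_lt(abs(mean(diffs[2, ]) - 0.5), 0.12)
  expect_error(roi_decoding_accuracy(NULL, integer(0)), "feature_set")
})

test_that("group F maps average across patients with hemisphere flips", {
  hm <- build_toy_head_model(8, 4, 1, seed = 9)
  mk <- function(vals) structure(list(f_values = vals), class = "f_map")
  f1 <- mk(c(1, 2, 3, 4, 10, 20, 30, 40))  # contra block then ipsi block
  f2 <- mk(rep(2, 8))
  g <- group_f_map(list(f1, f2), hm)
  expect_equal(g, (f1$f_values + 2) / 2)
  gf <- group_f_map(list(f1, f2), hm, flip = c(TRUE, FALSE))
  expect_equal(gf[1:4], (c(10, 20, 30, 40) + 2) / 2)
  expect_equal(gf[5:8], (c(1, 2, 3, 4) + 2) / 2)
})

test_that("contralateral F values dominate ipsilateral ones for planted bursts", {
  params <- cohort_session_params(seed = 11)
  hm <- params$head_model
  wins <- sapply(1:10, function(i) {
    sched <- make_task_schedule(5, 4, seed = 60 + i, sampling_rate = 100)
    rec <- simulate_session(hm, sched, d = 1.2, noise_sd = 1,
                            source_amp = params$source_amp, seed = 70 + i)
    filt <- estimate_inverse_filter(rec, hm, inverse_config(tol = 1e-4))
    fm <- vertex_f_map(apply_filter_and_zscore(filt, rec, 0, 500))
    mean(fm$f_values[select_roi(hm, "contra")]) >
      mean(fm$f_values[select_roi(hm, "ipsi")])
  })
  expect_gte(mean(wins), 0.95)
})
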