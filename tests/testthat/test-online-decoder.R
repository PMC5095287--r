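# one mid-size session shared by the decoder tests
decoder_fixture <- function(seed = 1, d = 1.2) {
  hm <- build_toy_head_model(12, 8, 0.5, seed = seed)
  sched <- make_task_schedule(5, 4, seed = seed + 1, sampling_rate = 200)
  rec <- simulate_session(hm, sched, d = d, noise_sd = 1, seed = seed + 2)
  list(hm = hm, rec = rec, feats = session_features(rec))
}

test_that("true-label decoder generalizes near its cross-validated estimate", {
  fx <- decoder_fixture(seed = 20)
  dec <- train_online_decoder(fx$feats, fx$rec, policy = "true_labels",
                              seed = 3)
  expect_equal(dec$policy, "true_labels")
  # score a fresh session from the same brain at the decoder's window
  pat <- class_patterns(fx$hm, "contra", seed = fx$rec$meta$seed)
  sched2 <- make_task_schedule(5, 4, seed = 91, sampling_rate = 200)
  rec2 <- simulate_session(fx$hm, sched2, d = 1.2, noise_sd = 1,
                           patterns = pat, seed = 92)
  f2 <- session_features(rec2)
  w <- match(dec$selected_window, f2$window_offsets)
  x2 <- matrix(f2$features[, w, ], ncol = dim(f2$features)[3])
  hit <- mean(predict(dec, x2, what = "class") == f2$labels)
  expect_gt(hit, 0.6)
  expect_lt(abs(hit - dec$cv_result$classification_accuracy), 0.2)
})

test_that("permuted-label decoder scores fresh data at chance", {
  fx <- decoder_fixture(seed = 30)
  dec <- train_online_decoder(fx$feats, fx$rec, policy = "permuted_labels",
                              seed = 5)
  pat <- class_patterns(fx$hm, "contra", seed = fx$rec$meta$seed)
  hits <- sapply(1:6, function(i) {
    sched2 <- make_task_schedule(3, 3, seed = 70 + i, sampling_rate = 200)
    rec2 <- simulate_session(fx$hm, sched2, d = 1.2, noise_sd = 1,
                             patterns = pat, seed = 80 + i)
    f2 <- session_features(rec2)
    w <- match(dec$selected_window, f2$window_offsets)
    x2 <- matrix(f2$features[, w, ], ncol = dim(f2$features)[3])
    mean(predict(dec, x2, what = "class") == f2$labels)
  })
  expect_lt(abs(mean(hits) - 0.5), 3 * sd(hits) / sqrt(6) + 0.05)
})

test_that("other_effector policy requires and uses intact-hand features", {
  fx <- decoder_fixture(seed = 40)
  expect_error(train_online_decoder(fx$feats, fx$rec,
                                    policy = "other_effector"),
               "intact_features")
  pat_i <- class_patterns(fx$hm, "ipsi", seed = 44)
  sched_i <- make_task_schedule(5, 4, seed = 45, sampling_rate = 200)
  rec_i <- simulate_session(fx$hm, sched_i, d = 1.2, noise_sd = 1,
                            active_hemi = "ipsi", patterns = pat_i, seed = 46)
  dec <- train_online_decoder(fx$feats, fx$rec, policy = "other_effector",
                              intact_features = session_features(rec_i),
                              seed = 6)
  expect_equal(dec$policy, "other_effector")
  expect_s3_class(dec, "online_decoder")
})

test_that("onset threshold calibration silences the resting state", {
  fx <- decoder_fixture(seed = 50)
  dec <- train_online_decoder(fx$feats, fx$rec, seed = 7)
  rest <- simulate_rest(fx$hm, duration_ms = 20000, sampling_rate = 200,
                        noise_sd = 1, seed = 51)
  thr <- calibrate_onset_threshold(dec, rest, margin = 0.01)
  scores <- attr(thr, "rest_scores")
  # smallest zero-detection threshold: max score plus the margin
  expect_equal(as.numeric(thr), max(scores) + 0.01)
  expect_equal(sum(scores >= as.numeric(thr)), 0)
  dec2 <- attr(thr, "decoder")
  expect_equal(dec2$onset_threshold, as.numeric(thr))
  expect_error(calibrate_onset_threshold(dec, simulate_rest(fx$hm, 5000,
    sampling_rate = 200, seed = 1)), "10 s")
})

test_that("the calibrated threshold rises with rest-stream noise", {
  # within the decoder's operating range; far outside it RBF scores saturate
  # toward the bias, so the monotone regime is the one the threshold is used in
  fx <- decoder_fixture(seed = 60)
  dec <- train_online_decoder(fx$feats, fx$rec, seed = 8)
  thr <- sapply(c(0.25, 0.5, 1), function(s) {
    mean(sapply(1:6, function(i) {
      rest <- simulate_rest(fx$hm, 15000, noise_sd = s, sampling_rate = 200,
                            seed = round(100 * s) + i)
      as.numeric(calibrate_onset_threshold(dec, rest))
    }))
  })
  expect_true(all(diff(thr) > 0))
})

test_that("onset detector separates movement windows from rest", {
  hm <- build_toy_head_model(12, 8, 0.5, seed = 70)
  sched <- make_task_schedule(5, 4, seed = 71, sampling_rate = 200)
  # clearly separable movement bursts (fixed amplitude above the noise floor)
  rec <- simulate_session(hm, sched, d = 1, noise_sd = 1, source_amp = 0.3,
                          seed = 72)
  fx <- list(hm = hm, rec = rec, feats = session_features(rec))
  dec <- train_online_decoder(fx$feats, fx$rec, seed = 9)
  f_on <- session_features(fx$rec, range = c(0, 500))
  x_move <- matrix(f_on$features[, 1, ], ncol = dim(f_on$features)[3])
  move_scores <- predict(dec, x_move, what = "onset")
  rest <- simulate_rest(fx$hm, 15000, sampling_rate = 200, seed = 71)
  thr <- calibrate_onset_threshold(dec, rest)
  expect_gt(mean(move_scores >= as.numeric(thr)), 0.8)
  expect_equal(sum(attr(thr, "rest_scores") >= as.numeric(thr)), 0)
})
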