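test_that("cohort structure follows the crossover design", {
  co <- simulate_cohort(n_patients = 3, signals = FALSE, seed = 1)
  expect_equal(nrow(co$pain), 9)  # patients x 3 conditions
  expect_equal(nrow(co$planted), 9)
  expect_setequal(unique(co$pain$condition), c("phantom", "random", "real"))
  expect_true(all(co$pain$vas_pre >= 0 & co$pain$vas_pre <= 100))
  expect_true(all(co$pain$vas_post >= 0 & co$pain$vas_post <= 100))
  # questionnaire totals are the sum of the four subscores
  subs <- paste0("mpq2_", c("continuous", "intermittent", "neuropathic",
                            "affective"), "_post")
  expect_equal(co$pain$mpq2_total_post, rowSums(co$pain[subs]))
})

test_that("default design is 10 patients and reproducible", {
  a <- simulate_cohort(signals = FALSE, seed = 5)
  expect_equal(a$n_patients, 10)
  expect_equal(nrow(a$pain), 30)
  expect_identical(a, simulate_cohort(signals = FALSE, seed = 5))
})

test_that("planted plasticity follows d_post = d_pre + delta_d (+ jitter)", {
  truth <- ground_truth(d_jitter_sd = 0)
  co <- simulate_cohort(n_patients = 4, truth = truth, signals = FALSE,
                        seed = 2)
  expect_true(all(co$planted$d_pre == 0.8))
  expect_equal(co$planted$d_post,
               pmax(0, 0.8 + truth$delta_d[co$planted$condition]),
               ignore_attr = TRUE)
  # jitter spreads the effect but keeps the condition means
  co2 <- simulate_cohort(n_patients = 30, truth = ground_truth(),
                         signals = FALSE, seed = 3)
  spread <- tapply(co2$planted$delta_d, co2$planted$condition, sd)
  expect_true(all(spread > 0.05 & spread < 0.35))
})

test_that("zero coupling and zero noise give exactly zero VAS change", {
  truth <- ground_truth(beta_pain = 0, pain_noise_sd = 0)
  co <- simulate_cohort(n_patients = 5, truth = truth, signals = FALSE,
                        seed = 4)
  expect_equal(co$pain$vas_post, co$pain$vas_pre)
})

test_that("cohort-mean VAS change is ordered real < random < phantom", {
  ord <- replicate(20, NA)
  for (i in 1:20) {
    co <- simulate_cohort(10, signals = FALSE, seed = 400 + i)
    m <- tapply(co$pain$vas_post - co$pain$vas_pre, co$pain$condition, mean)
    ord[i] <- m["real"] < m["random"] && m["random"] < m["phantom"]
  }
  expect_gte(mean(ord), 0.9)
})

test_that("only the continuous-pain subscore carries the planted coupling", {
  co <- simulate_cohort(60, signals = FALSE, seed = 6)
  dd <- co$planted$delta_d
  d_cont <- co$pain$mpq2_continuous_post - co$pain$mpq2_continuous_pre
  d_other <- co$pain$mpq2_intermittent_post - co$pain$mpq2_intermittent_pre
  expect_gt(cor(dd, d_cont), 0.4)
  expect_lt(abs(cor(dd, d_other)), 0.2)
})

test_that("cohort recordings reuse patient patterns across sessions", {
  co <- simulate_cohort(n_patients = 1, seed = 7,
                        params = cohort_session_params(seed = 7,
                                                       n_instructions_per_class = 2))
  pre <- co$sessions[[1]]$phantom$pre
  post <- co$sessions[[1]]$random$post
  expect_s3_class(pre, "session_recording")
  expect_equal(pre$meta$pattern_seed, post$meta$pattern_seed)
  expect_equal(pre$meta$d, co$planted$d_pre[1])
})

test_that("outcome deltas vanish when post equals pre", {
  co <- simulate_cohort(n_patients = 1, seed = 8,
                        params = cohort_session_params(seed = 8,
                                                       n_instructions_per_class = 3))
  for (cond in c("phantom", "random", "real"))
    co$sessions[[1]][[cond]]$post <- co$sessions[[1]][[cond]]$pre
  co$pain$vas_post <- co$pain$vas_pre
  out <- compute_outcomes(co)
  expect_true(all(out$table$delta_acc_contra == 0))
  expect_true(all(out$table$delta_acc_ipsi == 0))
  expect_true(all(abs(out$delta_f) < 1e-12))
  expect_true(all(out$table$delta_vas == 0))
})

test_that("outcomes require signal-level cohorts and matched pairs", {
  co <- simulate_cohort(n_patients = 2, signals = FALSE, seed = 9)
  expect_error(compute_outcomes(co), "signals = FALSE")
  co2 <- simulate_cohort(n_patients = 1, seed = 10,
                         params = cohort_session_params(seed = 10,
                                                        n_instructions_per_class = 2))
  co2$sessions[[1]]$random$post <- NULL
  expect_error(compute_outcomes(co2), "matched pre/post")
})

test_that("pain-noise calibration reports a sane operating point", {
  tr <- calibrate_pain_noise(ground_truth(), target_rho = 0.66, n_mc = 12,
                             seed = 11)
  cal <- attr(tr, "calibration")
  expect_gt(cal$slope, 0.1)
  expect_gt(cal$rho_max, 0.66)
  expect_gt(tr$pain_noise_sd, 0)
  expect_error(calibrate_pain_noise(ground_truth(), target_rho = 0.999,
                                    n_mc = 12, seed = 11), "attainable")
})
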