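# helper: a recording whose lead field is the identity (vertices == sensors),
# so the true currents are the sensor signals themselves
identity_recording <- function(seed = 1, n = 6, rate = 200, noise_sd = 1) {
  hm <- build_toy_head_model(n_sensors = n, n_vertices_per_hemi = n / 2,
                             roi_fraction = 1, seed = seed)
  hm$lead_field <- diag(n)
  sched <- mini_schedule(seed = seed, rate = rate)
  rec <- simulate_session(hm, sched, d = 1, noise_sd = noise_sd, seed = seed)
  list(hm = hm, rec = rec)
}

test_that("identity lead field with flat priors returns the sensor signals", {
  fx <- identity_recording(seed = 2)
  cfg <- inverse_config(baseline = "flat", noise_var = 1e-12, tol = 1e-10)
  filt <- suppressWarnings(estimate_inverse_filter(fx$rec, fx$hm, cfg))
  src <- project_recording(fx$rec, filt)
  err <- max(abs(src$signal - fx$rec$signal)) / max(abs(fx$rec$signal))
  expect_lt(err, 1e-6)
})

test_that("an isolated active vertex is localized at the true position", {
  # over-determined noiseless system; least-squares oracle gives the truth
  hm <- build_toy_head_model(n_sensors = 12, n_vertices_per_hemi = 3,
                             roi_fraction = 1, seed = 4)
  sched <- mini_schedule(seed = 4, rate = 200)
  rec <- simulate_session(hm, sched, d = 0, noise_sd = 1e-3, seed = 4)
  true_v <- 2
  j <- numeric(6); j[true_v] <- 1
  burst <- as.vector(hm$lead_field %*% j)
  cues <- execution_cues(rec$schedule)
  for (i in seq_len(nrow(cues))) {
    s0 <- floor(cues$time_ms[i] / 1000 * 200) + 1
    rec$signal[, s0:(s0 + 99)] <- rec$signal[, s0:(s0 + 99)] + burst
  }
  filt <- estimate_inverse_filter(rec, hm, inverse_config(tol = 1e-8))
  cf <- apply_filter_and_zscore(filt, rec, 0, 500)
  power <- colMeans(abs(matrix(cf$features[, 1, ], nrow = 12)))
  expect_equal(which.max(power), true_v)
  # least-squares oracle on the noiseless template
  ols <- qr.solve(hm$lead_field, burst)
  expect_equal(which.max(abs(ols)), true_v)
})

test_that("gamma0 -> Inf collapses to the closed-form Tikhonov filter", {
  fx <- identity_recording(seed = 5, n = 8)
  hm <- build_toy_head_model(n_sensors = 8, n_vertices_per_hemi = 6,
                             roi_fraction = 1, seed = 5)
  sched <- mini_schedule(seed = 5, rate = 200)
  rec <- simulate_session(hm, sched, d = 1, noise_sd = 1, seed = 5)
  cfg <- inverse_config(gamma0 = 1e10, baseline = "flat", flat_value = 0.7,
                        noise_var = 0.5, tol = 1e-10)
  filt <- estimate_inverse_filter(rec, hm, cfg)
  oracle <- ridge_filter(hm$lead_field, nu0 = 0.7, sigma2 = 0.5)
  expect_lt(max(abs(filt$filter - oracle)) / max(abs(oracle)), 1e-4)
})

test_that("the variational objective is non-decreasing across iterations", {
  hm <- build_toy_head_model(10, 8, 0.5, seed = 6)
  sched <- mini_schedule(seed = 6, rate = 200)
  rec <- simulate_session(hm, sched, d = 1.5, noise_sd = 1, seed = 6)
  # deliberately strict tolerance: runs to the iteration cap with a warning
  expect_warning(
    filt <- estimate_inverse_filter(rec, hm, inverse_config(tol = 1e-9,
                                                            max_iter = 30)),
    "max_iter")
  expect_gt(filt$iterations, 2)
  expect_true(all(diff(filt$objective) > -1e-6 * abs(filt$objective[-1])))
})

test_that("the inverse filter is linear and zero maps to zero", {
  hm <- mini_head_model(seed = 7)
  sched <- mini_schedule(seed = 7)
  rec <- simulate_session(hm, sched, d = 1, seed = 7)
  filt <- estimate_inverse_filter(rec, hm, inverse_config(tol = 1e-6))
  L <- filt$filter
  set.seed(8)
  x <- matrix(rnorm(nrow(hm$lead_field) * 5), ncol = 5)
  y <- matrix(rnorm(nrow(hm$lead_field) * 5), ncol = 5)
  expect_equal(L %*% (2 * x + 3 * y), 2 * L %*% x + 3 * L %*% y,
               tolerance = 1e-12)
  expect_true(all(L %*% matrix(0, nrow(hm$lead_field), 4) == 0))
  # doubling sensor input doubles raw currents
  expect_equal(L %*% (2 * x), 2 * (L %*% x), tolerance = 1e-12)
})

test_that("a planted contralateral burst yields lateralized currents", {
  params <- cohort_session_params(seed = 10)
  hm <- params$head_model
  lat <- replicate(5, NA_real_)
  for (i in 1:5) {
    sched <- make_task_schedule(3, 3, seed = 20 + i, sampling_rate = 100)
    rec <- simulate_session(hm, sched, d = 1, noise_sd = 1, seed = 30 + i)
    filt <- estimate_inverse_filter(rec, hm, inverse_config(tol = 1e-5))
    cf <- apply_filter_and_zscore(filt, rec, 0, 500)
    z0 <- matrix(cf$features[, 1, ], nrow = length(cf$labels))
    lat[i] <- mean(abs(z0[, select_roi(hm, "contra")])) -
      mean(abs(z0[, select_roi(hm, "ipsi")]))
  }
  expect_gt(mean(lat > 0), 0.8)
  expect_gt(mean(lat), 0)
})

test_that("degenerate configurations are rejected", {
  expect_error(inverse_config(m0 = -1), "positive")
  expect_error(inverse_config(gamma0 = 0), "positive")
  expect_error(inverse_config(data_span = c(-1000, 0)), "overlap")
  fx <- identity_recording(seed = 11)
  rest <- simulate_rest(fx$hm, duration_ms = 15000, sampling_rate = 200)
  expect_error(estimate_inverse_filter(rest, fx$hm), "no execution cues")
})
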