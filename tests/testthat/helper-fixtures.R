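# Small shared fixtures, built in code. The "mini" scale keeps unit tests in
# milliseconds; cohort-level checks use cohort_session_params().

mini_head_model <- function(seed = 1, n_sensors = 8, n_vertices = 4,
                            roi_fraction = 1) {
  build_toy_head_model(n_sensors, n_vertices, roi_fraction, seed = seed)
}

# 200 Hz, 3 instruction blocks x 2 cues per class = 6 trials/class
mini_schedule <- function(seed = 1, n_instr = 3, n_reps = 2, rate = 200) {
  make_task_schedule(n_instr, n_reps, seed = seed, sampling_rate = rate)
}

mini_session <- function(seed = 1, d = 1, noise_sd = 1, hm = mini_head_model(),
                         sched = mini_schedule(), ...) {
  simulate_session(hm, sched, d = d, noise_sd = noise_sd, seed = seed, ...)
}

# a feature set with known planted separation, bypassing the forward model:
# two Gaussian clouds separated by `sep` along the first channel
toy_features <- function(n_per_class = 12, n_win = 3, n_chan = 4, sep = 0,
                         seed = 1, offsets = NULL) {
  set.seed(seed)
  n <- 2 * n_per_class
  f <- array(rnorm(n * n_win * n_chan), dim = c(n, n_win, n_chan))
  labels <- factor(rep(c("grasp", "open"), each = n_per_class),
                   levels = c("grasp", "open"))
  f[labels == "grasp", , 1] <- f[labels == "grasp", , 1] + sep
  structure(list(features = f,
                 window_offsets = offsets %||% (100 * (seq_len(n_win) - 1)),
                 labels = labels, window = 500, step = 100,
                 sampling_rate = 1000, channels = seq_len(n_chan),
                 baseline_stats = NULL, zscored = TRUE),
            class = "feature_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fast_profile <- function() decode_profile("fast")
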