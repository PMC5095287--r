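#' Simulate a closed-loop BMI training session
#'
#' Streams a simulated brain through an online decoder for `duration_min`
#' minutes. The simulated patient intends grasp/open in alternating 5-s blocks
#' with a jittered movement onset per block; each intended movement adds a
#' 500-ms class-specific source burst at the current discriminability `d`.
#' Every `step_ms` the trailing 500-ms sensor window is averaged, z-scored
#' with the decoder's stored baseline statistics, gated by the onset detector
#' and, on a detection, classified; the prosthesis state switches to the
#' decoded class on detected onsets and is otherwise held. Decisions at time t
#' use only samples before t. Plasticity is applied as a single end-of-session
#' update: `final_d = d + delta_d`.
#'
#' @param decoder an [train_online_decoder()] object (threshold ideally set by
#'   [calibrate_onset_threshold()]).
#' @param head_model the simulated patient's head model.
#' @param patterns the patient's [class_patterns()].
#' @param d current discriminability of the simulated brain.
#' @param delta_d plasticity applied at session end (the decoder condition's
#'   effect).
#' @param duration_min session length in minutes (default 10).
#' @param step_ms decision stride.
#' @param sampling_rate Hz of the simulated stream.
#' @param noise_sd sensor noise s.d.
#' @param block_ms intention block length.
#' @param refractory_ms suppression of further detections after an onset.
#' @param source_amp,onset_gain burst amplitude and class-common gain
#'   (defaults as in [simulate_session()]).
#' @param seed integer seed.
#' @return object of class `loop_trace`: `trace` data.frame (`time_ms`,
#'   `onset_detected`, `decoded_class`, `true_intended_class`,
#'   `prosthesis_state`), `summary` (onset count, class agreement rate),
#'   `final_d`.
#' @export
run_closed_loop <- function(decoder, head_model, patterns, d, delta_d = 0,
                            duration_min = 10, step_ms = 100,
                            sampling_rate = 1000, noise_sd = 1,
                            block_ms = 5000, refractory_ms = 1000,
                            source_amp = NULL, onset_gain = 3, seed = 1) {
  stopifnot(inherits(decoder, "online_decoder"),
            inherits(head_model, "head_model"),
            inherits(patterns, "class_patterns"))
  assert_number(d, "d", lower = 0)
  assert_number(duration_min, "duration_min")
  if (duration_min <= 0) stop("`duration_min` must be > 0", call. = FALSE)
  rate <- sampling_rate
  n_samp <- ceiling(duration_min * 60 * rate)
  if (is.null(source_amp)) source_amp <- default_source_amp(rate, noise_sd)
  G <- head_model$lead_field
  gu <- as.vector(G %*% patterns$u)
  gw <- as.vector(G %*% patterns$w)
  template <- list(grasp = source_amp * (onset_gain * gu + (d / 2) * gw),
                   open  = source_amp * (onset_gain * gu - (d / 2) * gw))
  burst_len <- round(0.5 * rate)

  n_blocks <- ceiling(duration_min * 60000 / block_ms)
  block_class <- rep(c("grasp", "open"), length.out = n_blocks)

  stream <- with_seed(seed, {
    x <- matrix(rnorm(nrow(G) * n_samp, sd = noise_sd), nrow(G), n_samp)
    onset_ms <- (seq_len(n_blocks) - 1) * block_ms + runif(n_blocks, 0, 1000)
    for (b in seq_len(n_blocks)) {
      s0 <- floor(onset_ms[b] / 1000 * rate) + 1L
      idx <- s0:min(s0 + burst_len - 1L, n_samp)
      x[, idx] <- x[, idx] + template[[block_class[b]]]
    }
    x
  })

  # trailing-window means at every decision step, then z-scoring
  wl <- round(decoder$window / 1000 * rate)
  sl <- round(step_ms / 1000 * rate)
  starts <- seq(1L, n_samp - wl + 1L, by = sl)
  times_ms <- (starts + wl - 1L) / rate * 1000  # decision uses samples <= t
  wm <- window_means(t(stream), starts, wl)
  z <- sweep(sweep(wm, 2, decoder$baseline_stats$mean), 2,
             decoder$baseline_stats$sd, "/")
  dec <- predict(decoder, z, what = "both")

  intended <- block_class[pmin(floor(times_ms / block_ms) + 1L, n_blocks)]
  n_steps <- length(starts)
  # the class decision for a detected onset is taken `class_delay` steps
  # later, when the trailing window covers the movement burst (still causal:
  # the prosthesis moves at that later step)
  class_delay <- max(0L, round(400 / step_ms))
  state <- character(n_steps)
  onset <- logical(n_steps)
  decided <- rep(NA_character_, n_steps)
  cur <- "idle"
  refr_until <- -Inf
  for (k in seq_len(n_steps)) {
    if (dec$onset[k] && times_ms[k] >= refr_until) {
      onset[k] <- TRUE
      kk <- min(k + class_delay, n_steps)
      decided[k] <- as.character(dec$class[kk])
      cur <- decided[k]
      refr_until <- times_ms[k] + refractory_ms
    }
    state[k] <- cur
  }
  agreement <- if (any(onset))
    mean(decided[onset] == intended[onset]) else NA_real_

  trace <- data.frame(time_ms = times_ms, onset_detected = onset,
                      decoded_class = ifelse(onset, decided,
                                             as.character(dec$class)),
                      true_intended_class = intended,
                      prosthesis_state = state)
  structure(list(trace = trace,
                 summary = list(n_onsets = sum(onset),
                                agreement_rate = agreement,
                                n_steps = n_steps),
                 final_d = max(0, d + delta_d), d = d, seed = seed),
            class = "loop_trace")
}

#' @export
print.loop_trace <- function(x, ...) {
  cat(sprintf(
    "<loop_trace> %d steps, %d onsets, agreement %.3f, final d = %.2f\n",
    x$summary$n_steps, x$summary$n_onsets,
    x$summary$agreement_rate %||% NA, x$final_d))
  invisible(x)
}
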