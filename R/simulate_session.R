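#' Class-specific cortical activation patterns
#'
#' Draws the two fixed spatial patterns that define the movement classes on the
#' sensorimotor ROI of one hemisphere: a common activation pattern `u` and a
#' difference pattern `w`. Both live on the ROI vertices only and are scaled so
#' their sensor projections (`lead_field %*% u`, `lead_field %*% w`) are unit
#' norm and mutually orthogonal, so one scalar `d` controls class separation in
#' sensor space while the trial-averaged source stays independent of `d`.
#'
#' @param head_model a [build_toy_head_model()] object.
#' @param hemisphere hemisphere carrying the activation.
#' @param seed integer seed; patterns are meant to be fixed per simulated
#'   patient and reused across that patient's sessions.
#' @return object of class `class_patterns`: vertex-length vectors `u`, `w`.
#' @export
class_patterns <- function(head_model, hemisphere = c("contra", "ipsi"),
                           seed = 1) {
  stopifnot(inherits(head_model, "head_model"))
  hemisphere <- match.arg(hemisphere)
  roi <- select_roi(head_model, hemisphere)
  if (length(roi) < 2L)
    stop("need at least 2 ROI vertices to build two class patterns", call. = FALSE)
  G <- head_model$lead_field
  nv <- ncol(G)
  with_seed(seed, {
    u <- numeric(nv); w <- numeric(nv)
    u[roi] <- rnorm(length(roi))
    w[roi] <- rnorm(length(roi))
    gu <- as.vector(G %*% u)
    u <- u / sqrt(sum(gu^2))
    gu <- as.vector(G %*% u)
    # orthogonalize the sensor image of w against that of u (stays in ROI span)
    gw <- as.vector(G %*% w)
    w <- w - u * sum(gw * gu)
    gw <- as.vector(G %*% w)
    w <- w / sqrt(sum(gw^2))
    structure(list(u = u, w = w, hemisphere = hemisphere, roi = roi, seed = seed),
              class = "class_patterns")
  })
}

default_source_amp <- function(sampling_rate, noise_sd, effect_scale = 1.5) {
  # expresses the burst amplitude as a fixed effect size in z-scored feature
  # space: class separation there is ~ d * effect_scale regardless of rate;
  # a noiseless session keeps a unit reference scale
  effect_scale * (if (noise_sd > 0) noise_sd else 1) / sqrt(0.5 * sampling_rate)
}

#' Simulate one offline-task sensor recording
#'
#' Generates a continuous multichannel recording: i.i.d. Gaussian sensor noise
#' everywhere, plus, at every execution cue, a rectangular 0-500 ms source
#' burst on the active hemisphere's sensorimotor ROI. The burst source is
#' `amp * (u +/- (d/2) * w)` (sign by movement class), so the separation of the
#' two class templates in sensor space is `d * amp` while their (signed)
#' trial average `amp * u` does not depend on `d`. The initial rest baseline
#' contains noise only.
#'
#' @param head_model a [build_toy_head_model()] object.
#' @param schedule a [make_task_schedule()] object.
#' @param d planted class discriminability (dimensionless, >= 0).
#' @param noise_sd sensor noise standard deviation.
#' @param active_hemi hemisphere carrying the movement-related source.
#' @param patterns optional [class_patterns()]; defaults to patterns derived
#'   from `seed` (pass explicitly to keep them fixed across a patient's
#'   sessions).
#' @param source_amp burst amplitude; the default scales with
#'   `noise_sd / sqrt(window samples)` so the z-scored effect size is
#'   rate-independent (~`1.5 * d`).
#' @param onset_gain amplitude of the class-common activation `u` relative to
#'   `source_amp`. Movement-evoked fields are much larger than their
#'   class-discriminative part; the common component is what the move-vs-rest
#'   onset detector keys on, and it cancels from every between-class
#'   contrast.
#' @param duration_ms recording length; defaults to the schedule's own
#'   duration. An explicit value shorter than the schedule is an error.
#' @param seed integer seed.
#'
#' @return object of class `session_recording`: `signal` (sensors x samples),
#'   `sampling_rate`, `schedule`, `selected_channels`, and a `meta` list.
#' @export
simulate_session <- function(head_model, schedule, d = 0.8, noise_sd = 1,
                             active_hemi = c("contra", "ipsi"), patterns = NULL,
                             source_amp = NULL, onset_gain = 3,
                             duration_ms = NULL, seed = 1) {
  stopifnot(inherits(head_model, "head_model"),
            inherits(schedule, "task_schedule"))
  active_hemi <- match.arg(active_hemi)
  assert_number(d, "d", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  rate <- schedule$sampling_rate
  if (is.null(duration_ms)) duration_ms <- schedule$duration_ms
  if (duration_ms < schedule$duration_ms)
    stop(sprintf("schedule (%.0f ms) exceeds requested duration (%.0f ms)",
                 schedule$duration_ms, duration_ms), call. = FALSE)
  if (is.null(patterns)) patterns <- class_patterns(head_model, active_hemi, seed)
  stopifnot(inherits(patterns, "class_patterns"),
            patterns$hemisphere == active_hemi)
  if (is.null(source_amp)) source_amp <- default_source_amp(rate, noise_sd)

  G <- head_model$lead_field
  n_sens <- nrow(G)
  n_samp <- ceiling(duration_ms / 1000 * rate)
  burst_len <- round(0.5 * rate)

  # sensor-space class templates
  gu <- as.vector(G %*% patterns$u)
  gw <- as.vector(G %*% patterns$w)
  template <- list(grasp = source_amp * (onset_gain * gu + (d / 2) * gw),
                   open  = source_amp * (onset_gain * gu - (d / 2) * gw))

  signal <- with_seed(seed, {
    x <- matrix(rnorm(n_sens * n_samp, sd = noise_sd), n_sens, n_samp)
    cues <- execution_cues(schedule)
    for (i in seq_len(nrow(cues))) {
      s0 <- floor(cues$time_ms[i] / 1000 * rate) + 1L
      idx <- s0:(s0 + burst_len - 1L)
      x[, idx] <- x[, idx] + template[[cues$label[i]]]
    }
    x
  })

  structure(list(signal = signal, sampling_rate = rate, schedule = schedule,
                 selected_channels = seq_len(n_sens),
                 meta = list(d = d, noise_sd = noise_sd, source_amp = source_amp,
                             onset_gain = onset_gain,
                             active_hemi = active_hemi, seed = seed,
                             pattern_seed = patterns$seed, space = "sensor")),
            class = "session_recording")
}

#' Simulate a rest-only recording
#'
#' Pure sensor noise with an event-free schedule; used for calibrating the
#' onset-detector threshold against the resting state.
#'
#' @inheritParams simulate_session
#' @param duration_ms length of the rest stream.
#' @return a `session_recording` whose schedule has no execution cues.
#' @export
simulate_rest <- function(head_model, duration_ms = 20000, noise_sd = 1,
                          sampling_rate = 1000, seed = 1) {
  stopifnot(inherits(head_model, "head_model"))
  n_sens <- nrow(head_model$lead_field)
  n_samp <- ceiling(duration_ms / 1000 * sampling_rate)
  signal <- with_seed(seed,
    matrix(rnorm(n_sens * n_samp, sd = noise_sd), n_sens, n_samp))
  schedule <- structure(list(
    events = data.frame(time_ms = numeric(0), kind = character(0),
                        label = character(0)),
    baseline_span = c(0, duration_ms), sampling_rate = sampling_rate,
    duration_ms = duration_ms, n_instructions_per_class = 0L, n_reps = 0L,
    seed = seed), class = "task_schedule")
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 schedule = schedule, selected_channels = seq_len(n_sens),
                 meta = list(d = 0, noise_sd = noise_sd, seed = seed,
                             space = "sensor")),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> %d channels x %d samples @ %g Hz, %d execution cues, d = %g\n",
    nrow(x$signal), ncol(x$signal), x$sampling_rate,
    nrow(execution_cues(x$schedule)), x$meta$d %||% NA))
  invisible(x)
}
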