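#' Extract cue-locked epochs
#'
#' Cuts one segment per execution cue, `t_start` to `t_end` ms relative to the
#' cue. The cue time maps to a sample index by rounding down and segments are
#' closed-open `[t_start, t_end)` in sample space, so a -500..1000 ms epoch at
#' 1,000 Hz holds exactly 1,500 samples. Only the recording's
#' `selected_channels` are carried forward.
#'
#' @param recording a `session_recording`.
#' @param t_start,t_end epoch limits in ms relative to each execution cue.
#' @return object of class `epoch_set`: `data` array (samples x channels x
#'   trials), `labels` factor, `t_start`, `sampling_rate`.
#' @examples
#' hm <- build_toy_head_model(4, 2, 1, seed = 1)
#' rec <- simulate_session(hm, make_task_schedule(1, 2, seed = 1,
#'                                                sampling_rate = 200))
#' dim(extract_epochs(rec, -500, 1000)$data)
#' @export
extract_epochs <- function(recording, t_start = -500, t_end = 1000) {
  stopifnot(inherits(recording, "session_recording"))
  if (t_start >= t_end) stop("`t_start` must be < `t_end`", call. = FALSE)
  rate <- recording$sampling_rate
  cues <- execution_cues(recording$schedule)
  chans <- recording$selected_channels
  n_samp <- round((t_end - t_start) / 1000 * rate)
  n_total <- ncol(recording$signal)

  data <- array(NA_real_, dim = c(n_samp, length(chans), nrow(cues)))
  for (i in seq_len(nrow(cues))) {
    cue_idx <- floor(cues$time_ms[i] / 1000 * rate) + 1L
    from <- cue_idx + round(t_start / 1000 * rate)
    to <- from + n_samp - 1L
    if (from < 1L || to > n_total)
      stop(sprintf("epoch window [%g, %g) ms of cue %d lies outside the recording",
                   t_start, t_end, i), call. = FALSE)
    data[, , i] <- t(recording$signal[chans, from:to, drop = FALSE])
  }
  structure(list(data = data,
                 labels = factor(cues$label, levels = c("grasp", "open")),
                 t_start = t_start, t_end = t_end, sampling_rate = rate,
                 channels = chans),
            class = "epoch_set")
}

# window means of a samples x channels matrix at given start samples (1-based),
# window length wl, via cumulative sums; brute-force-verified in the tests
window_means <- function(x, starts, wl) {
  cs <- apply(x, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(x))
  cs <- rbind(0, cs)
  (cs[starts + wl, , drop = FALSE] - cs[starts, , drop = FALSE]) / wl
}

#' Sliding-window averaging of epochs
#'
#' Averages each epoch in windows of `window` ms slid by `step` ms; the number
#' of windows is `floor((span - window)/step) + 1` and each feature is the
#' arithmetic mean of the samples in its closed-open window.
#'
#' @param epochs an [extract_epochs()] object.
#' @param window,step window length and slide in ms.
#' @return object of class `feature_set`: `features` array (trials x windows x
#'   channels), `window_offsets` (ms of window starts relative to the cue),
#'   `labels`, `window`, `step`; not yet z-scored.
#' @export
sliding_window_average <- function(epochs, window = 500, step = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  assert_number(window, "window", lower = 1)
  assert_number(step, "step", lower = 1)
  rate <- epochs$sampling_rate
  span <- epochs$t_end - epochs$t_start
  if (window > span) stop("`window` exceeds the epoch span", call. = FALSE)
  wl <- round(window / 1000 * rate)
  sl <- round(step / 1000 * rate)
  n_win <- floor((span - window) / step) + 1
  starts <- 1L + sl * (seq_len(n_win) - 1L)
  offsets <- epochs$t_start + step * (seq_len(n_win) - 1)

  n_trials <- dim(epochs$data)[3]
  n_chan <- dim(epochs$data)[2]
  feats <- array(NA_real_, dim = c(n_trials, n_win, n_chan))
  for (tr in seq_len(n_trials))
    feats[tr, , ] <- window_means(matrix(epochs$data[, , tr], ncol = n_chan),
                                  starts, wl)
  structure(list(features = feats, window_offsets = offsets,
                 labels = epochs$labels, window = window, step = step,
                 sampling_rate = rate, channels = epochs$channels,
                 baseline_stats = NULL, zscored = FALSE),
            class = "feature_set")
}

#' Baseline statistics of a recording
#'
#' Tiles the recording's rest baseline (by default the initial 50 s) with the
#' same sliding windows used for the features and returns the per-channel mean
#' and standard deviation of those window means.
#'
#' @param recording a `session_recording`.
#' @param window,step windowing parameters, ms.
#' @return list with `mean`, `sd` (per channel) and the windowing used.
#' @export
baseline_stats <- function(recording, window = 500, step = 100) {
  stopifnot(inherits(recording, "session_recording"))
  rate <- recording$sampling_rate
  span <- recording$schedule$baseline_span
  from <- floor(span[1] / 1000 * rate) + 1L
  to <- min(floor(span[2] / 1000 * rate), ncol(recording$signal))
  x <- t(recording$signal[recording$selected_channels, from:to, drop = FALSE])
  if (nrow(x) < 2L) stop("baseline span holds fewer than 2 samples", call. = FALSE)
  wl <- round(window / 1000 * rate)
  sl <- round(step / 1000 * rate)
  if (nrow(x) < wl) stop("baseline span shorter than one window", call. = FALSE)
  starts <- seq(1L, nrow(x) - wl + 1L, by = sl)
  wm <- window_means(x, starts, wl)
  mu <- colMeans(wm)
  sig <- apply(wm, 2, sd)
  bad <- which(sig == 0)
  if (length(bad))
    stop(sprintf("zero baseline s.d. in channel(s) %s",
                 paste(recording$selected_channels[bad], collapse = ", ")),
         call. = FALSE)
  list(mean = mu, sd = sig, window = window, step = step,
       channels = recording$selected_channels)
}

#' Baseline z-scoring of window features
#'
#' Converts window-averaged features to z-scores, `z = (x - mu)/sigma` per
#' channel, with `mu`/`sigma` estimated from the session's own rest baseline
#' (see [baseline_stats()]) or supplied explicitly.
#'
#' @param features a [sliding_window_average()] `feature_set`.
#' @param recording the session the baseline is taken from; ignored when
#'   `stats` is given.
#' @param stats optional precomputed [baseline_stats()].
#' @return the `feature_set` with z-scored `features` and `baseline_stats` set.
#' @export
baseline_zscore <- function(features, recording = NULL, stats = NULL) {
  stopifnot(inherits(features, "feature_set"))
  if (is.null(stats)) {
    if (is.null(recording))
      stop("either `recording` or `stats` must be supplied", call. = FALSE)
    stats <- baseline_stats(recording, features$window, features$step)
  }
  if (length(stats$mean) != dim(features$features)[3])
    stop("baseline stats do not match the feature channels", call. = FALSE)
  f <- features$features
  for (ch in seq_along(stats$mean))
    f[, , ch] <- (f[, , ch] - stats$mean[ch]) / stats$sd[ch]
  features$features <- f
  features$baseline_stats <- stats
  features$zscored <- TRUE
  features
}

#' Full sensor-feature pipeline for one session
#'
#' Convenience chain: [extract_epochs()], [sliding_window_average()],
#' [baseline_zscore()]. The `"offline"` range is -500..1000 ms (11 windows);
#' `"online"` is -2000..1000 ms, the range the online decoder is built from.
#'
#' @param recording a `session_recording`.
#' @param range `"offline"`, `"online"`, or a numeric `c(t_start, t_end)` ms.
#' @param window,step windowing parameters, ms.
#' @return a z-scored `feature_set`.
#' @export
session_features <- function(recording, range = "offline", window = 500,
                             step = 100) {
  lim <- if (is.numeric(range)) range
         else switch(match.arg(range, c("offline", "online")),
                     offline = c(-500, 1000), online = c(-2000, 1000))
  ep <- extract_epochs(recording, lim[1], lim[2])
  baseline_zscore(sliding_window_average(ep, window, step), recording)
}

#' @export
print.feature_set <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<feature_set> %d trials x %d windows x %d channels (%s)\n",
              d[1], d[2], d[3],
              if (isTRUE(x$zscored)) "z-scored" else "raw window means"))
  invisible(x)
}
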