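#' Build the offline movement-task schedule
#'
#' Reproduces the cue structure of the offline task: after an initial 50-s rest
#' baseline, instruction blocks alternate in randomized class order. Each block
#' holds a 3-s fixation cross, a 1-s instruction word (`grasp` or `open`), two
#' 1-s timing cues, and then `n_reps` execution cues spaced 5.5 s apart. With
#' the defaults (10 instructions per class, 4 execution cues each) every class
#' receives 40 execution cues.
#'
#' @param n_instructions_per_class instruction blocks per movement class.
#' @param n_reps execution cues within each instruction block.
#' @param seed integer seed controlling the class order.
#' @param sampling_rate Hz of the recording the schedule is destined for.
#' @param baseline_ms initial rest period (default 50 s).
#'
#' @return An object of class `task_schedule`: `events` data.frame
#'   (`time_ms`, `kind`, `label`), `baseline_span` (ms), `sampling_rate`,
#'   and `duration_ms` (schedule end plus a 2-s tail).
#' @examples
#' sched <- make_task_schedule(2, 2, seed = 1)
#' table(subset(sched$events, kind == "execution_cue")$label)
#' @export
make_task_schedule <- function(n_instructions_per_class = 10, n_reps = 4,
                               seed = 1, sampling_rate = 1000,
                               baseline_ms = 50000) {
  n_instructions_per_class <- assert_count(n_instructions_per_class,
                                           "n_instructions_per_class")
  n_reps <- assert_count(n_reps, "n_reps")
  assert_number(sampling_rate, "sampling_rate", lower = 1)
  assert_number(baseline_ms, "baseline_ms", lower = 0)

  classes <- with_seed(seed,
    sample(rep(c("grasp", "open"), n_instructions_per_class)))

  rows <- vector("list", length(classes))
  t <- baseline_ms
  for (i in seq_along(classes)) {
    cl <- classes[i]
    exec_t <- t + 6000 + 5500 * (seq_len(n_reps) - 1)
    rows[[i]] <- data.frame(
      time_ms = c(t, t + 3000, t + 4000, t + 5000, exec_t),
      kind = c("fixation", "instruction", "timing_cue", "timing_cue",
               rep("execution_cue", n_reps)),
      label = c("none", cl, "none", "none", rep(cl, n_reps)),
      stringsAsFactors = FALSE)
    t <- t + 6000 + 5500 * n_reps  # 5.5-s gap after the last cue, then next block
  }
  events <- do.call(rbind, rows)
  stopifnot(!is.unsorted(events$time_ms, strictly = TRUE))

  structure(list(events = events,
                 baseline_span = c(0, baseline_ms),
                 sampling_rate = sampling_rate,
                 duration_ms = t + 2000,
                 n_instructions_per_class = n_instructions_per_class,
                 n_reps = n_reps, seed = seed),
            class = "task_schedule")
}

#' Execution-cue table of a schedule
#' @param schedule a `task_schedule`.
#' @return data.frame with `time_ms` and `label` of the execution cues.
#' @export
execution_cues <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  ev <- schedule$events
  ev[ev$kind == "execution_cue", c("time_ms", "label")]
}

#' @export
print.task_schedule <- function(x, ...) {
  cues <- execution_cues(x)
  cat(sprintf("<task_schedule> %d events, %d execution cues (%s), %.1f s total\n",
              nrow(x$events), nrow(cues),
              paste(sprintf("%s: %d", names(table(cues$label)),
                            table(cues$label)), collapse = ", "),
              x$duration_ms / 1000))
  invisible(x)
}
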