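#' Write a session recording to a plain-text directory container
#'
#' Serializes a session as `signal.csv` (samples x channels), `events.csv`
#' and `meta.json` under `dir`. Plain-text by design so containers stay
#' inspectable and diffable; intended for toy/cohort problem sizes.
#'
#' @param recording a `session_recording`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(recording, dir) {
  stopifnot(inherits(recording, "session_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- data.table::as.data.table(t(recording$signal))
  data.table::setnames(sig, paste0("ch", seq_len(ncol(sig))))
  data.table::fwrite(sig, file.path(dir, "signal.csv"))
  data.table::fwrite(recording$schedule$events, file.path(dir, "events.csv"))
  meta <- list(sampling_rate = recording$sampling_rate,
               baseline_span = recording$schedule$baseline_span,
               duration_ms = recording$schedule$duration_ms,
               selected_channels = recording$selected_channels,
               meta = recording$meta)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a session recording written by [write_session()]
#'
#' @param dir the container directory.
#' @return a `session_recording`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  sig <- t(as.matrix(data.table::fread(file.path(dir, "signal.csv"))))
  dimnames(sig) <- NULL
  events <- as.data.frame(data.table::fread(file.path(dir, "events.csv"),
                                            colClasses = list(
                                              character = c("kind", "label"))))
  schedule <- structure(list(events = events,
                             baseline_span = meta$baseline_span,
                             sampling_rate = meta$sampling_rate,
                             duration_ms = meta$duration_ms,
                             seed = meta$meta$seed),
                        class = "task_schedule")
  structure(list(signal = sig, sampling_rate = meta$sampling_rate,
                 schedule = schedule,
                 selected_channels = meta$selected_channels,
                 meta = meta$meta),
            class = "session_recording")
}

#' Write a cohort manifest (and optionally its sessions)
#'
#' Writes `manifest.csv` with one row per patient x condition x session role,
#' carrying the session path and the pre/post pain scores (VAS and the
#' SF-MPQ2 total and four subscores). With `write_signals = TRUE` every
#' session is serialized via [write_session()] into subdirectories.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param dir target directory.
#' @param write_signals also write the raw session containers.
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort_manifest <- function(cohort, dir, write_signals = FALSE) {
  stopifnot(inherits(cohort, "bmi_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cohort$pain))) {
    p <- cohort$pain$patient[i]; cond <- cohort$pain$condition[i]
    for (role in c("pre", "post")) {
      path <- file.path(sprintf("p%02d", p), cond, role)
      if (write_signals && !is.null(cohort$sessions))
        write_session(cohort$sessions[[p]][[cond]][[role]],
                      file.path(dir, path))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(patient_id = p, condition = cond, session_role = role,
                   path = path),
        cohort$pain[i, !(names(cohort$pain) %in% c("patient", "condition"))])
    }
  }
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Export a per-vertex map as a CSV table
#'
#' @param values per-vertex values (e.g. F values or correlation map).
#' @param head_model the `head_model` supplying labels.
#' @param file target CSV path.
#' @return the exported data.frame, invisibly.
#' @export
write_vertex_map <- function(values, head_model, file) {
  stopifnot(inherits(head_model, "head_model"))
  df <- data.frame(vertex_id = seq_along(values),
                   hemisphere = head_model$vertex_hemi,
                   roi = head_model$vertex_region, value = values)
  data.table::fwrite(df, file)
  invisible(df)
}

#' Write a table of decoding results as CSV
#'
#' One row per session: the window-resolved accuracies, the nested-CV
#' classification accuracy and the selected window.
#'
#' @param results named list of `decoding_result` objects.
#' @param file target CSV path.
#' @return the exported data.frame, invisibly.
#' @export
write_decoding_results <- function(results, file) {
  stopifnot(length(results) >= 1L)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    stopifnot(inherits(r, "decoding_result"))
    acc <- as.list(r$accuracy_by_window)
    names(acc) <- paste0("acc_", names(r$accuracy_by_window), "ms")
    cbind(data.frame(session_id = names(results)[i] %||% i,
                     classification_accuracy = r$classification_accuracy,
                     selected_window = r$selected_window,
                     n_trials = r$n_trials), as.data.frame(acc))
  })
  out <- do.call(rbind, rows)
  data.table::fwrite(out, file)
  invisible(out)
}
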