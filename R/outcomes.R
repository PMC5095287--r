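#' Pre/post plasticity outcomes for a simulated cohort
#'
#' Runs the source-level analysis pipeline on every patient x condition pair
#' of a cohort: estimates an inverse filter per session, z-scores the windowed
#' cortical currents against the session's own baseline, computes the
#' per-vertex F map at the 0-500 ms post-cue window, decodes movement type
#' from the contralateral and ipsilateral sensorimotor ROI currents, and
#' assembles the post-minus-pre changes together with the pain records.
#'
#' @param cohort a [simulate_cohort()] object generated with `signals = TRUE`.
#' @param profile a [decode_profile()]; the cohort Monte-Carlos use `"fast"`.
#' @param config an [inverse_config()].
#' @param metrics character subset of `c("acc_contra", "acc_ipsi", "fmap",
#'   "current")`; dropping metrics skips their computation.
#' @return object of class `cohort_outcomes`: `table` (one row per patient x
#'   condition with `delta_acc_contra`, `delta_acc_ipsi`, `delta_current`,
#'   `delta_vas`, `delta_mpq2_*`), `delta_f` (vertices x pairs matrix),
#'   `delta_current_map` (vertices x pairs), `head_model`.
#' @export
compute_outcomes <- function(cohort, profile = decode_profile("fast"),
                             config = inverse_config(tol = 1e-4),
                             metrics = c("acc_contra", "acc_ipsi", "fmap",
                                         "current")) {
  stopifnot(inherits(cohort, "bmi_cohort"))
  if (is.null(cohort$sessions))
    stop("cohort was generated with signals = FALSE; no recordings to analyse",
         call. = FALSE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  hm <- cohort$head_model
  roi_contra <- select_roi(hm, "contra")
  roi_ipsi <- select_roi(hm, "ipsi")
  nv <- ncol(hm$lead_field)
  conditions <- c("phantom", "random", "real")

  rows <- list()
  n_pairs <- cohort$n_patients * length(conditions)
  delta_f <- if ("fmap" %in% metrics) matrix(NA_real_, nv, n_pairs) else NULL
  delta_cur <- if ("current" %in% metrics) matrix(NA_real_, nv, n_pairs) else NULL
  i <- 0L

  analyse <- function(rec) {
    filt <- estimate_inverse_filter(rec, hm, config)
    cf <- apply_filter_and_zscore(filt, rec, profile$range[1],
                                  profile$range[2], profile$window,
                                  profile$step)
    w0 <- match(0, cf$window_offsets)
    if (is.na(w0))
      stop("decode profile must include the 0 ms window", call. = FALSE)
    out <- list()
    if ("acc_contra" %in% metrics)
      out$acc_contra <- roi_decoding_accuracy(cf, roi_contra, profile,
        seed = rec$meta$seed)$classification_accuracy
    if ("acc_ipsi" %in% metrics)
      out$acc_ipsi <- roi_decoding_accuracy(cf, roi_ipsi, profile,
        seed = rec$meta$seed)$classification_accuracy
    if ("fmap" %in% metrics)
      out$f <- vertex_f_map(cf, offset = 0)$f_values
    if ("current" %in% metrics)
      out$cur <- colMeans(matrix(cf$features[, w0, ], ncol = nv))
    out
  }

  for (p in seq_len(cohort$n_patients)) {
    for (cond in conditions) {
      i <- i + 1L
      pair <- cohort$sessions[[p]][[cond]]
      if (is.null(pair$pre) || is.null(pair$post))
        stop(sprintf("patient %d condition %s lacks a matched pre/post pair",
                     p, cond), call. = FALSE)
      pre <- analyse(pair$pre)
      post <- analyse(pair$post)
      pain <- cohort$pain[cohort$pain$patient == p &
                            cohort$pain$condition == cond, ]
      row <- data.frame(patient = p, condition = cond)
      if ("acc_contra" %in% metrics) {
        row$acc_contra_pre <- pre$acc_contra
        row$acc_contra_post <- post$acc_contra
        row$delta_acc_contra <- post$acc_contra - pre$acc_contra
      }
      if ("acc_ipsi" %in% metrics)
        row$delta_acc_ipsi <- post$acc_ipsi - pre$acc_ipsi
      if ("fmap" %in% metrics) {
        delta_f[, i] <- post$f - pre$f
        row$delta_f_contra <- mean(delta_f[roi_contra, i])
        row$delta_f_ipsi <- mean(delta_f[roi_ipsi, i])
      }
      if ("current" %in% metrics) {
        delta_cur[, i] <- post$cur - pre$cur
        row$delta_current <- mean(delta_cur[roi_contra, i])
      }
      row$delta_vas <- pain$vas_post - pain$vas_pre
      row$delta_mpq2_total <- pain$mpq2_total_post - pain$mpq2_total_pre
      for (s in c("continuous", "intermittent", "neuropathic", "affective"))
        row[[paste0("delta_mpq2_", s)]] <-
          pain[[paste0("mpq2_", s, "_post")]] - pain[[paste0("mpq2_", s, "_pre")]]
      rows[[i]] <- row
    }
  }

  structure(list(table = do.call(rbind, rows), delta_f = delta_f,
                 delta_current_map = delta_cur, head_model = hm,
                 profile = profile, metrics = metrics),
            class = "cohort_outcomes")
}

#' @export
print.cohort_outcomes <- function(x, ...) {
  cat(sprintf("<cohort_outcomes> %d patient x condition pairs; metrics: %s\n",
              nrow(x$table), paste(x$metrics, collapse = ", ")))
  if ("delta_acc_contra" %in% names(x$table)) {
    agg <- stats::aggregate(delta_acc_contra ~ condition, x$table, mean)
    cat("  mean delta accuracy (contra):",
        paste(sprintf("%s %.3f", agg$condition, agg$delta_acc_contra),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.cohort_outcomes <- function(x, ...) {
  tab <- x$table
  if (!all(c("delta_acc_contra", "delta_vas") %in% names(tab)))
    stop("outcomes lack delta_acc_contra/delta_vas", call. = FALSE)
  cols <- c(phantom = "red", random = "grey40", real = "blue")
  graphics::plot(tab$delta_acc_contra, tab$delta_vas,
                 col = cols[tab$condition], pch = 16,
                 xlab = expression(Delta * "accuracy (contra ROI)"),
                 ylab = expression(Delta * "VAS"), ...)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}
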