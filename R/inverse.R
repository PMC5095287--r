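#' Configuration of the hierarchical variational-Bayes inverse
#'
#' Parameters of the source-current estimator. The per-vertex current
#' variances carry an inverse-gamma hyperprior centred on `m0` times the
#' baseline-estimated variance with confidence `gamma0`; `m0 = 100`,
#' `gamma0 = 10` follow the published settings. `data_span` is the post-cue
#' interval (ms) whose trials feed the filter estimation, `baseline_span` the
#' pre-cue interval the baseline current variance is estimated from.
#'
#' @param m0 prior scale of the current-variance hyperparameter (> 0).
#' @param gamma0 prior confidence of the current-variance hyperparameter
#'   (> 0); as `gamma0 -> Inf` the estimate collapses to the fixed-variance
#'   Tikhonov (minimum-norm) filter.
#' @param data_span,baseline_span ms relative to the execution cue; must not
#'   overlap.
#' @param max_iter,tol iteration cap and relative objective-change tolerance.
#' @param noise_var sensor noise variance; `NULL` estimates it from the
#'   session's rest baseline.
#' @param baseline `"estimate"` derives the baseline current variance from the
#'   pre-cue signals through a minimum-norm reference inverse; `"flat"` uses
#'   the constant `flat_value` for every vertex (a flat prior).
#' @param flat_value variance used under `baseline = "flat"`.
#' @return a list of class `inverse_config`.
#' @export
inverse_config <- function(m0 = 100, gamma0 = 10, data_span = c(0, 1000),
                           baseline_span = c(-1500, -500), max_iter = 200,
                           tol = 1e-6, noise_var = NULL,
                           baseline = c("estimate", "flat"), flat_value = 1) {
  assert_number(m0, "m0"); assert_number(gamma0, "gamma0")
  assert_number(tol, "tol")
  if (m0 <= 0 || gamma0 <= 0 || tol <= 0)
    stop("`m0`, `gamma0` and `tol` must be positive", call. = FALSE)
  if (max(baseline_span) > min(data_span) &&
      min(baseline_span) < max(data_span))
    stop("`data_span` and `baseline_span` must not overlap", call. = FALSE)
  structure(list(m0 = m0, gamma0 = gamma0, data_span = data_span,
                 baseline_span = baseline_span,
                 max_iter = assert_count(max_iter, "max_iter"), tol = tol,
                 noise_var = noise_var, baseline = match.arg(baseline),
                 flat_value = flat_value),
            class = "inverse_config")
}

# concatenate the [span) ms segments of every execution-cue epoch
concat_epoch_span <- function(recording, span) {
  ep <- extract_epochs(recording, span[1], span[2])
  d <- dim(ep$data)
  if (d[3] == 0L) stop("no execution cues to estimate from", call. = FALSE)
  # samples x channels x trials -> channels x (samples * trials)
  matrix(aperm(ep$data, c(2, 1, 3)), nrow = d[2])
}

#' Estimate the linear inverse filter by variational Bayes
#'
#' Estimates per-vertex current variances with an automatic-relevance-style
#' EM scheme and returns the corresponding linear inverse filter. The model is
#' `y_t = G j_t + noise`, `j_v ~ N(0, nu_v)`, with an inverse-gamma hyperprior
#' on `nu_v` whose mode is the baseline variance scaled by `m0` and whose
#' confidence is `gamma0`. Each iteration alternates the posterior current
#' estimate given the variances (E-step) with the closed-form variance update
#' `nu_v <- (S_v + gamma0 * nu0_v) / (T + gamma0)` (M-step), which shrinks the
#' empirical per-vertex energy `S_v` toward the baseline prior. The penalized
#' marginal log-likelihood is non-decreasing across iterations and serves as
#' the convergence criterion.
#'
#' In the limits the estimator reduces to textbook solutions: `gamma0 -> Inf`
#' gives the fixed-variance Tikhonov (minimum-norm) filter, and an identity
#' lead field with negligible noise returns the sensor signals unchanged.
#'
#' @param recording a `session_recording` (its `selected_channels` are used).
#' @param head_model the `head_model` supplying the lead field.
#' @param config an [inverse_config()].
#' @return object of class `inverse_filter`: `filter` (vertices x channels),
#'   `nu` (converged current variances), `nu0` (prior variances),
#'   `noise_var`, `objective` (per-iteration trace), `converged`,
#'   `iterations`.
#' @export
estimate_inverse_filter <- function(recording, head_model,
                                    config = inverse_config()) {
  stopifnot(inherits(recording, "session_recording"),
            inherits(head_model, "head_model"),
            inherits(config, "inverse_config"))
  chans <- recording$selected_channels
  G <- head_model$lead_field[chans, , drop = FALSE]
  nv <- ncol(G); ns <- nrow(G)

  Y <- concat_epoch_span(recording, config$data_span)
  Tn <- ncol(Y)

  sigma2 <- config$noise_var
  if (is.null(sigma2)) {
    rate <- recording$sampling_rate
    span <- recording$schedule$baseline_span
    bl <- recording$signal[chans,
      (floor(span[1] / 1000 * rate) + 1):floor(span[2] / 1000 * rate),
      drop = FALSE]
    sigma2 <- mean(apply(bl, 1, var))
  }
  sigma2 <- max(sigma2, 1e-12)

  nu0 <- if (config$baseline == "flat") rep(config$flat_value, nv) else {
    # baseline current variance through a minimum-norm reference inverse
    Yb <- concat_epoch_span(recording, config$baseline_span)
    L0 <- t(G) %*% solve(tcrossprod(G) + sigma2 * diag(ns))
    base_var <- rowSums((L0 %*% tcrossprod(Yb)) * L0) / ncol(Yb)
    config$m0 * pmax(base_var, 1e-12)
  }

  nu <- nu0
  objective <- numeric(0)
  converged <- FALSE
  YYt <- tcrossprod(Y)  # sensor covariance sufficient statistic
  for (it in seq_len(config$max_iter)) {
    M <- t(G * rep(nu, each = ns))              # nu * G', vertices x sensors
    Sy <- G %*% M + sigma2 * diag(ns)
    ch <- tryCatch(chol(Sy), error = function(e)
      stop("singular sensor covariance; lead field or priors degenerate",
           call. = FALSE))
    Syi <- chol2inv(ch)
    L <- M %*% Syi                              # inverse filter at current nu
    dSig <- nu - rowSums(L * M)                 # posterior variance diagonal
    S <- rowSums((L %*% YYt) * L) + Tn * dSig   # = sum_t <j_vt^2>

    logdet <- 2 * sum(log(diag(ch)))
    fit <- -0.5 * (Tn * (logdet + ns * log(2 * pi)) + sum(Syi * YYt))
    pen <- -0.5 * config$gamma0 * sum(log(nu) + nu0 / nu)
    objective <- c(objective, fit + pen)

    nu_new <- pmax((S + config$gamma0 * nu0) / (Tn + config$gamma0), 1e-12)
    if (it > 1) {
      rel <- abs(objective[it] - objective[it - 1]) /
        (abs(objective[it - 1]) + .Machine$double.eps)
      if (rel < config$tol) { converged <- TRUE; break }
    }
    nu <- nu_new
  }
  if (!converged && config$max_iter > 1)
    warning(sprintf("inverse estimation stopped at max_iter = %d (relative objective change %.2e)",
                    config$max_iter,
                    abs(diff(tail(objective, 2))) / abs(tail(objective, 2)[1])))

  M <- t(G * rep(nu, each = ns))
  Sy <- G %*% M + sigma2 * diag(ns)
  L <- M %*% chol2inv(chol(Sy))

  structure(list(filter = L, nu = nu, nu0 = nu0, noise_var = sigma2,
                 objective = objective, converged = converged,
                 iterations = length(objective), config = config,
                 channels = chans),
            class = "inverse_filter")
}

#' Closed-form fixed-variance (Tikhonov / minimum-norm) filter
#'
#' The `gamma0 -> Inf` limit of [estimate_inverse_filter()], computed directly:
#' `L = N G' (G N G' + sigma2 I)^-1` with `N = diag(nu0)`. Exposed as the
#' analytic reference the iterative estimator is tested against.
#'
#' @param G lead field (sensors x vertices).
#' @param nu0 per-vertex prior variances (recycled).
#' @param sigma2 noise variance.
#' @return vertices x sensors filter matrix.
#' @export
ridge_filter <- function(G, nu0 = 1, sigma2 = 1e-6) {
  nv <- ncol(G); ns <- nrow(G)
  nu0 <- rep_len(nu0, nv)
  M <- t(G * rep(nu0, each = ns))
  M %*% solve(G %*% M + sigma2 * diag(ns))
}

#' Project a recording into source space through an inverse filter
#'
#' Applies the filter to the (selected-channel) sensor signal and returns a
#' `session_recording` whose "channels" are the source vertices, so the whole
#' preprocessing stack (epoching, windowing, baseline z-scoring) applies
#' unchanged to cortical currents. Linear by construction.
#'
#' @param recording a sensor-space `session_recording`.
#' @param filter an `inverse_filter` (or bare vertices x channels matrix).
#' @return a source-space `session_recording`.
#' @export
project_recording <- function(recording, filter) {
  stopifnot(inherits(recording, "session_recording"))
  L <- if (inherits(filter, "inverse_filter")) filter$filter else as.matrix(filter)
  cur <- L %*% recording$signal[recording$selected_channels, , drop = FALSE]
  out <- recording
  out$signal <- cur
  out$selected_channels <- seq_len(nrow(cur))
  out$meta$space <- "source"
  out
}

#' Estimate, window and z-score cortical currents
#'
#' Applies the inverse filter to each trial's sensor signals, averages the
#' currents in sliding windows and z-scores every vertex against the currents
#' of the session's initial rest baseline (estimated through the same filter).
#' The window starting at 0 ms (the 0-500 ms post-cue mean) is the per-trial
#' analysis feature used for the discriminability maps.
#'
#' @param filter an `inverse_filter` from [estimate_inverse_filter()].
#' @param recording the sensor-space session.
#' @param t_start,t_end epoch range, ms relative to the execution cue.
#' @param window,step windowing, ms.
#' @return a z-scored source-space `feature_set` (trials x windows x
#'   vertices); errors if any vertex has zero baseline variance.
#' @export
apply_filter_and_zscore <- function(filter, recording, t_start = -500,
                                    t_end = 1000, window = 500, step = 100) {
  src <- project_recording(recording, filter)
  feats <- session_features(src, range = c(t_start, t_end),
                            window = window, step = step)
  attr(feats, "space") <- "source"
  feats
}

#' @export
print.inverse_filter <- function(x, ...) {
  cat(sprintf(
    "<inverse_filter> %d vertices x %d channels, %d iterations (%s), objective %.4g\n",
    nrow(x$filter), ncol(x$filter), x$iterations,
    if (x$converged) "converged" else "not converged", tail(x$objective, 1)))
  invisible(x)
}
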