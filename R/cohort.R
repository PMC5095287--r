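#' Ground-truth parameters of a simulated patient cohort
#'
#' Describes the planted structure of a simulated crossover study: baseline
#' class discriminability `d_pre`, the per-condition plasticity effect
#' `delta_d` applied by closed-loop training with each decoder type, an
#' optional per-patient Gaussian jitter on that effect, and a linear Gaussian
#' pain model in which the change in the 0-100 visual-analogue pain score is
#' `beta_pain` times the realized discriminability change plus noise. Among
#' the four short-form McGill Pain Questionnaire 2 subscores only the
#' continuous-pain subscore carries the coupling (`beta_mpq2`); the others are
#' pure noise.
#'
#' @param d_pre baseline discriminability (>= 0).
#' @param delta_d named per-condition change; by default the phantom decoder
#'   raises, the random decoder leaves, and the real-hand decoder lowers
#'   discriminability.
#' @param d_jitter_sd per-patient s.d. of the plasticity effect.
#' @param beta_pain VAS units per unit discriminability change (> 0 means the
#'   phantom decoder increases pain).
#' @param pain_noise_sd s.d. of the VAS change noise.
#' @param beta_mpq2,mpq2_noise_sd coupling and noise of the continuous-pain
#'   subscore changes.
#' @param vas_pre_mean,vas_pre_sd distribution of baseline VAS (clipped to
#'   0-100).
#' @return a list of class `ground_truth`.
#' @export
ground_truth <- function(d_pre = 0.8,
                         delta_d = c(phantom = 0.5, random = 0, real = -0.5),
                         d_jitter_sd = 0.15, beta_pain = 15, pain_noise_sd = 5,
                         beta_mpq2 = 6, mpq2_noise_sd = 2,
                         vas_pre_mean = 38, vas_pre_sd = 12) {
  assert_number(d_pre, "d_pre", lower = 0)
  if (!all(c("phantom", "random", "real") %in% names(delta_d)))
    stop("`delta_d` needs named entries phantom/random/real", call. = FALSE)
  assert_number(d_jitter_sd, "d_jitter_sd", lower = 0)
  assert_number(pain_noise_sd, "pain_noise_sd", lower = 0)
  structure(list(d_pre = d_pre, delta_d = delta_d[c("phantom", "random", "real")],
                 d_jitter_sd = d_jitter_sd, beta_pain = beta_pain,
                 pain_noise_sd = pain_noise_sd, beta_mpq2 = beta_mpq2,
                 mpq2_noise_sd = mpq2_noise_sd, vas_pre_mean = vas_pre_mean,
                 vas_pre_sd = vas_pre_sd),
            class = "ground_truth")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Cohort-scale session parameters
#'
#' The problem size used for cohort-level Monte-Carlo studies: a 16-sensor /
#' 40-vertex head model, 100 Hz sampling, and the study's 10 instruction
#' blocks of 4 execution cues per class (40 trials per class). The burst
#' amplitude is set so that source-space decoding of a pre-training session
#' sits near 70% accuracy, the level the published sensorimotor-current
#' decoding operates at. The full-scale single-session configuration
#' (1,000 Hz, 32 sensors) remains the default of the individual generators.
#'
#' @param seed integer seed for the shared head model.
#' @param n_instructions_per_class,effect_scale overridable design knobs.
#' @return list with `head_model`, `sampling_rate`, `n_instructions_per_class`,
#'   `n_reps`, `noise_sd`, `source_amp`.
#' @export
cohort_session_params <- function(seed = 1, n_instructions_per_class = 10,
                                  effect_scale = 2) {
  rate <- 100
  list(head_model = build_toy_head_model(16, 20, 0.5, seed = seed),
       sampling_rate = rate,
       n_instructions_per_class = n_instructions_per_class, n_reps = 4,
       noise_sd = 1,
       source_amp = default_source_amp(rate, 1, effect_scale = effect_scale))
}

#' Simulate a three-condition crossover cohort
#'
#' Generates `n_patients` patients, each undergoing the phantom / random /
#' real-hand decoder conditions with a pre- and post-training offline session.
#' Post-session discriminability is `d_pre + delta_d[condition]` plus the
#' per-patient jitter (floored at 0); the same patient-specific activation
#' patterns are reused across that patient's sessions. Pain records follow
#' the linear model in [ground_truth()]; the mean post-cue source amplitude is
#' identical across conditions by construction, so the mean current change is
#' uncoupled from pain.
#'
#' @param n_patients number of patients (default 10).
#' @param truth a [ground_truth()].
#' @param params session-scale parameters, see [cohort_session_params()].
#' @param signals generate raw recordings (`TRUE`) or only outcome-level
#'   quantities — realized discriminabilities and pain records (`FALSE`).
#' @param seed integer seed.
#' @return object of class `bmi_cohort`: `sessions[[patient]][[condition]]`
#'   with `pre`/`post` recordings (when `signals`), `pain` data.frame,
#'   `planted` data.frame of realized discriminabilities, `head_model`,
#'   `truth`.
#' @export
simulate_cohort <- function(n_patients = 10, truth = ground_truth(),
                            params = cohort_session_params(), signals = TRUE,
                            seed = 1) {
  n_patients <- assert_count(n_patients, "n_patients")
  stopifnot(inherits(truth, "ground_truth"))
  conditions <- c("phantom", "random", "real")
  seeds <- derive_seeds(seed, 3L)
  hm <- params$head_model

  grid <- expand.grid(patient = seq_len(n_patients), condition = conditions,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$patient), ]
  n_pairs <- nrow(grid)

  planted <- with_seed(seeds[1], {
    jit <- rnorm(n_pairs, 0, truth$d_jitter_sd)
    d_pre <- rep(truth$d_pre, n_pairs)
    d_post <- pmax(0, d_pre + truth$delta_d[grid$condition] + jit)
    data.frame(grid, d_pre = d_pre, d_post = d_post,
               delta_d = d_post - d_pre, row.names = NULL)
  })

  pain <- with_seed(seeds[2], {
    vas_pre_pat <- clip(rnorm(n_patients, truth$vas_pre_mean, truth$vas_pre_sd),
                        0, 100)
    sub_means <- c(continuous = 8, intermittent = 5, neuropathic = 5,
                   affective = 3)
    sub_sds <- c(continuous = 2.5, intermittent = 2, neuropathic = 2,
                 affective = 1.5)
    out <- planted[c("patient", "condition")]
    out$vas_pre <- vas_pre_pat[planted$patient]
    dvas <- truth$beta_pain * planted$delta_d +
      rnorm(n_pairs, 0, truth$pain_noise_sd)
    out$vas_post <- clip(out$vas_pre + dvas, 0, 100)
    for (s in names(sub_means)) {
      pre <- pmax(0, rnorm(n_pairs, sub_means[s], sub_sds[s]))
      shift <- if (s == "continuous")
        truth$beta_mpq2 * planted$delta_d +
          rnorm(n_pairs, 0, truth$mpq2_noise_sd)
      else rnorm(n_pairs, 0, 0.75 * truth$mpq2_noise_sd)
      out[[paste0("mpq2_", s, "_pre")]] <- pre
      out[[paste0("mpq2_", s, "_post")]] <- pmax(0, pre + shift)
    }
    out$mpq2_total_pre <- rowSums(out[paste0("mpq2_", names(sub_means), "_pre")])
    out$mpq2_total_post <- rowSums(out[paste0("mpq2_", names(sub_means), "_post")])
    out
  })

  sessions <- NULL
  if (signals) {
    schedule_seeds <- derive_seeds(seeds[3], 2L * n_pairs + n_patients)
    sessions <- vector("list", n_patients)
    for (p in seq_len(n_patients)) {
      pat <- class_patterns(hm, "contra", seed = schedule_seeds[2L * n_pairs + p])
      sessions[[p]] <- list()
      for (ci in seq_along(conditions)) {
        row <- which(planted$patient == p & planted$condition == conditions[ci])
        s_pre <- schedule_seeds[2L * (row - 1L) + 1L]
        s_post <- schedule_seeds[2L * row]
        make <- function(d, s) {
          sched <- make_task_schedule(params$n_instructions_per_class,
                                      params$n_reps, seed = s,
                                      sampling_rate = params$sampling_rate)
          simulate_session(hm, sched, d = d, noise_sd = params$noise_sd,
                           patterns = pat, source_amp = params$source_amp,
                           seed = s)
        }
        sessions[[p]][[conditions[ci]]] <-
          list(pre = make(planted$d_pre[row], s_pre),
               post = make(planted$d_post[row], s_post))
      }
    }
  }

  structure(list(sessions = sessions, pain = pain, planted = planted,
                 head_model = hm, truth = truth, params = params,
                 n_patients = n_patients, seed = seed),
            class = "bmi_cohort")
}

#' @export
print.bmi_cohort <- function(x, ...) {
  cat(sprintf("<bmi_cohort> %d patients x 3 conditions (%s recordings)\n",
              x$n_patients, if (is.null(x$sessions)) "without" else "with"))
  invisible(x)
}

#' Calibrate the pain-noise level for a target accuracy-pain correlation
#'
#' The population Pearson correlation between the measured decoding-accuracy
#' change and the VAS change depends on how noisily accuracy is estimated.
#' This routine measures that by Monte-Carlo: it simulates patient-condition
#' pairs under `truth`, runs the decoding pipeline on each pre/post pair,
#' regresses the accuracy change on the realized discriminability change to
#' obtain the response slope `g` and residual s.d. `sigma_eps`, and then
#' solves the linear-model correlation identity
#' \deqn{\rho^2 = (\beta g v)^2 / ((g^2 v + \sigma_\epsilon^2)(\beta^2 v + \sigma_\eta^2))}
#' (with `v` the variance of the planted discriminability change across the
#' design) for the pain noise `sigma_eta` that yields the requested `rho`.
#'
#' @param truth a [ground_truth()]; its `beta_pain` is kept.
#' @param target_rho desired population correlation (0, 1).
#' @param params session parameters ([cohort_session_params()]).
#' @param profile decoding profile for the Monte-Carlo and downstream use.
#' @param n_mc Monte-Carlo patient-condition pairs.
#' @param seed integer seed.
#' @return the `ground_truth` with `pain_noise_sd` replaced; diagnostics
#'   (slope, residual s.d., maximal attainable rho) in attribute
#'   `calibration`.
#' @export
calibrate_pain_noise <- function(truth, target_rho = 0.66,
                                 params = cohort_session_params(),
                                 profile = decode_profile("fast"), n_mc = 45,
                                 seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  assert_number(target_rho, "target_rho")
  if (target_rho <= 0 || target_rho >= 1)
    stop("`target_rho` must be in (0, 1)", call. = FALSE)
  hm <- params$head_model
  roi <- select_roi(hm, "contra")
  conditions <- rep(c("phantom", "random", "real"), length.out = n_mc)
  seeds <- derive_seeds(seed, 3L * n_mc + 1L)

  dd <- da <- numeric(n_mc)
  jit <- with_seed(seeds[3L * n_mc + 1L], rnorm(n_mc, 0, truth$d_jitter_sd))
  for (i in seq_len(n_mc)) {
    d_pre <- truth$d_pre
    d_post <- max(0, d_pre + truth$delta_d[conditions[i]] + jit[i])
    pat <- class_patterns(hm, "contra", seed = seeds[3L * i - 2L])
    decode_one <- function(d, s) {
      sched <- make_task_schedule(params$n_instructions_per_class,
                                  params$n_reps, seed = s,
                                  sampling_rate = params$sampling_rate)
      rec <- simulate_session(hm, sched, d = d, noise_sd = params$noise_sd,
                              patterns = pat, source_amp = params$source_amp,
                              seed = s)
      filt <- estimate_inverse_filter(rec, hm, inverse_config(tol = 1e-4))
      cf <- apply_filter_and_zscore(filt, rec, profile$range[1],
                                    profile$range[2], profile$window,
                                    profile$step)
      roi_decoding_accuracy(cf, roi, profile, seed = s)$classification_accuracy
    }
    dd[i] <- d_post - d_pre
    da[i] <- decode_one(d_post, seeds[3L * i]) -
      decode_one(d_pre, seeds[3L * i - 1L])
  }

  fit <- stats::lm(da ~ dd)
  g <- coef(fit)[2]
  sigma_eps2 <- mean(fit$residuals^2)
  # population variance of the planted change across the balanced design
  v <- mean((truth$delta_d - mean(truth$delta_d))^2) + truth$d_jitter_sd^2
  var_a <- g^2 * v + sigma_eps2
  rho_max <- abs(g) * sqrt(v / var_a)
  if (target_rho >= rho_max)
    stop(sprintf(
      "target rho %.2f exceeds the attainable maximum %.2f at this problem size",
      target_rho, rho_max), call. = FALSE)
  beta <- truth$beta_pain
  sigma_eta2 <- beta^2 * v * (g^2 * v / (target_rho^2 * var_a) - 1)
  out <- truth
  out$pain_noise_sd <- sqrt(sigma_eta2)
  attr(out, "calibration") <- list(slope = unname(g),
                                   sigma_eps = sqrt(sigma_eps2),
                                   var_delta_d = v, rho_max = rho_max,
                                   n_mc = n_mc)
  out
}
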