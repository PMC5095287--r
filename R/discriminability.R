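#' Per-vertex one-way ANOVA F map
#'
#' Classic one-way ANOVA `F = MS_between / MS_within` computed independently
#' at every vertex (or channel) from the per-trial window-mean features of the
#' window starting at `offset` ms — by default the 0-500 ms post-cue mean.
#' Vertices with zero within-class variance but distinct class means are
#' reported as `+Inf` and flagged in the `degenerate` field rather than left
#' as silent `NaN`s.
#'
#' @param features a (source- or sensor-space) `feature_set`.
#' @param offset window start, ms; must be one of the feature windows.
#' @param labels optional class factor overriding the feature labels.
#' @return object of class `f_map`: `f_values` (one per vertex, >= 0),
#'   `df` (between, within), `offset`, `degenerate` flags.
#' @export
vertex_f_map <- function(features, offset = 0, labels = NULL) {
  stopifnot(inherits(features, "feature_set"))
  w <- match(offset, features$window_offsets)
  if (is.na(w))
    stop(sprintf("offset %g ms is not a feature window", offset), call. = FALSE)
  labels <- droplevels(labels %||% features$labels)
  k <- nlevels(labels)
  if (k < 2L) stop("need >= 2 classes", call. = FALSE)
  if (any(table(labels) < 2L)) stop("need >= 2 trials per class", call. = FALSE)

  x <- matrix(features$features[, w, ], nrow = length(labels))
  n <- nrow(x)
  grand <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (cl in levels(labels)) {
    rows <- labels == cl
    m <- colMeans(x[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (m - grand)^2
    ssw <- ssw + colSums(sweep(x[rows, , drop = FALSE], 2, m)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- msb / msw
  degenerate <- msw == 0
  f[degenerate & msb > 0] <- Inf
  f[degenerate & msb == 0] <- 0
  structure(list(f_values = f, df = c(between = k - 1L, within = n - k),
                 offset = offset, degenerate = degenerate, n = n),
            class = "f_map")
}

#' @export
print.f_map <- function(x, ...) {
  cat(sprintf("<f_map> %d vertices, df = (%d, %d), max F = %.2f\n",
              length(x$f_values), x$df[1], x$df[2],
              suppressWarnings(max(x$f_values[is.finite(x$f_values)]))))
  invisible(x)
}

#' Decoding configuration profiles
#'
#' Bundles the cross-validation settings used when decoding is embedded in
#' larger analyses. `"full"` is the primary configuration: -500..1000 ms
#' epochs, 11 windows of 500 ms slid by 100 ms, 10-fold outer CV with 10x
#' repeated 10-fold inner CV over a 3x3 hyperparameter grid. `"fast"` is the
#' cohort-study configuration used in the Monte-Carlo analyses: the single
#' informative 0-500 ms window, fixed hyperparameters and 5-fold CV (the
#' nested selection degenerates gracefully when there is nothing to select).
#'
#' @param profile `"full"` or `"fast"`.
#' @return a list of class `decode_profile`.
#' @export
decode_profile <- function(profile = c("full", "fast")) {
  profile <- match.arg(profile)
  out <- if (profile == "full") {
    list(range = c(-500, 1000), window = 500, step = 100, k_outer = 10,
         k_inner = 10, inner_repeats = 10, costs = c(0.1, 1, 10),
         gamma_scale = c(0.1, 1, 10))
  } else {
    list(range = c(0, 500), window = 500, step = 100, k_outer = 5,
         k_inner = 1, inner_repeats = 1, costs = 10, gamma_scale = 1)
  }
  out$name <- profile
  structure(out, class = "decode_profile")
}

#' ROI-restricted source-space decoding accuracy
#'
#' Restricts z-scored cortical-current features to the given ROI vertices and
#' delegates to [nested_cv_accuracy()], i.e. decodes movement type from the
#' currents of one hemisphere's sensorimotor cortex exactly as done for the
#' sensor signals.
#'
#' @param current_features source-space `feature_set` from
#'   [apply_filter_and_zscore()].
#' @param roi vertex ids, e.g. from [select_roi()].
#' @param profile a [decode_profile()].
#' @param seed integer seed.
#' @return a `decoding_result`.
#' @export
roi_decoding_accuracy <- function(current_features, roi,
                                  profile = decode_profile("full"), seed = 1) {
  stopifnot(inherits(current_features, "feature_set"))
  if (length(roi) == 0L) stop("`roi` is empty", call. = FALSE)
  if (max(roi) > dim(current_features$features)[3])
    stop("`roi` indexes vertices beyond the feature set", call. = FALSE)
  sub <- current_features
  sub$features <- current_features$features[, , roi, drop = FALSE]
  sub$channels <- roi
  if (!is.null(sub$baseline_stats)) {
    sub$baseline_stats$mean <- sub$baseline_stats$mean[roi]
    sub$baseline_stats$sd <- sub$baseline_stats$sd[roi]
  }
  nested_cv_accuracy(sub, k_outer = profile$k_outer, k_inner = profile$k_inner,
                     inner_repeats = profile$inner_repeats,
                     costs = profile$costs,
                     gammas = profile$gamma_scale / length(roi),
                     seed = seed)
}

#' Group-average F map across patients
#'
#' Vertex-wise mean of per-patient F maps after mapping each patient's
#' affected side to the canonical (contra) hemisphere: patients flagged in
#' `flip` have their hemispheres swapped before averaging, the synthetic
#' analogue of mirroring the two left-affected patients onto the group
#' template. All simulated patients share one head model, so registration is
#' the identity and a flip is an exchange of the two hemisphere blocks.
#'
#' @param f_maps list of [vertex_f_map()] results on the same head model.
#' @param head_model the shared `head_model`.
#' @param flip logical per patient; `TRUE` swaps hemispheres.
#' @return numeric vector of mean F per vertex.
#' @export
group_f_map <- function(f_maps, head_model, flip = NULL) {
  stopifnot(inherits(head_model, "head_model"), length(f_maps) >= 1L)
  nv <- ncol(head_model$lead_field)
  flip <- flip %||% rep(FALSE, length(f_maps))
  stopifnot(length(flip) == length(f_maps))
  contra <- which(head_model$vertex_hemi == "contra")
  ipsi <- which(head_model$vertex_hemi == "ipsi")
  if (length(contra) != length(ipsi))
    stop("hemisphere flip needs equally sized hemispheres", call. = FALSE)
  acc <- matrix(NA_real_, nv, length(f_maps))
  for (i in seq_along(f_maps)) {
    f <- f_maps[[i]]$f_values
    if (length(f) != nv) stop("F map does not match the head model", call. = FALSE)
    if (flip[i]) f[c(contra, ipsi)] <- f[c(ipsi, contra)]
    acc[, i] <- f
  }
  rowMeans(acc)
}
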