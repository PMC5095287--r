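#' Build a toy two-hemisphere head model
#'
#' Constructs a parametric source space (two clusters of cortical vertices, one
#' per hemisphere, with a labelled sensorimotor region of interest) together
#' with a sensor array and a forward model. The lead field is a smooth
#' distance-decay (Gaussian) kernel from each vertex to each sensor, so sensor
#' output is exactly linear in the vertex currents. Hemispheres are labelled
#' `contra`/`ipsi` relative to the affected (phantom) hand.
#'
#' The toy geometry replaces subject anatomy: vertices are drawn inside two
#' balls centred at x = -1 (contra) and x = +1 (ipsi), sensors on a sphere of
#' radius 2. Within each hemisphere the `roi_fraction` of vertices closest to
#' the hemisphere centroid are labelled `sensorimotor`, the rest `other`.
#'
#' @param n_sensors number of sensors (>= 2).
#' @param n_vertices_per_hemi number of source vertices per hemisphere (>= 2).
#' @param roi_fraction fraction (0, 1] of each hemisphere's vertices labelled
#'   as the sensorimotor region of interest.
#' @param seed integer seed; identical seeds give bitwise-identical models.
#' @param decay length scale of the Gaussian distance-decay lead field.
#'
#' @return An object of class `head_model`: list with `vertex_positions`
#'   (vertices x 3), `vertex_hemi` (`contra`/`ipsi`), `vertex_region`
#'   (`sensorimotor`/`other`), `sensor_positions` (sensors x 3) and
#'   `lead_field` (sensors x vertices).
#' @examples
#' hm <- build_toy_head_model(n_sensors = 8, n_vertices_per_hemi = 4, seed = 1)
#' dim(hm$lead_field)
#' @export
build_toy_head_model <- function(n_sensors = 32, n_vertices_per_hemi = 40,
                                 roi_fraction = 0.5, seed = 1, decay = 1) {
  n_sensors <- assert_count(n_sensors, "n_sensors", min = 2L)
  n_vertices_per_hemi <- assert_count(n_vertices_per_hemi, "n_vertices_per_hemi",
                                      min = 2L)
  assert_number(roi_fraction, "roi_fraction")
  if (roi_fraction <= 0 || roi_fraction > 1)
    stop("`roi_fraction` must be in (0, 1]", call. = FALSE)

  with_seed(seed, {
    centers <- rbind(contra = c(-1, 0, 0), ipsi = c(1, 0, 0))
    nv <- 2L * n_vertices_per_hemi
    hemi <- rep(c("contra", "ipsi"), each = n_vertices_per_hemi)
    vpos <- matrix(0, nv, 3)
    region <- character(nv)
    for (h in 1:2) {
      rows <- which(hemi == rownames(centers)[h])
      pts <- matrix(rnorm(3 * n_vertices_per_hemi, sd = 0.4),
                    n_vertices_per_hemi, 3)
      vpos[rows, ] <- sweep(pts, 2, centers[h, ], "+")
      # ROI: vertices nearest the hemisphere centroid
      d <- sqrt(rowSums(sweep(vpos[rows, , drop = FALSE], 2, centers[h, ])^2))
      n_roi <- max(1L, ceiling(roi_fraction * n_vertices_per_hemi - 1e-9))
      roi <- rows[order(d)][seq_len(n_roi)]
      region[rows] <- "other"
      region[roi] <- "sensorimotor"
    }
    sdir <- matrix(rnorm(3 * n_sensors), n_sensors, 3)
    sdir <- sdir / sqrt(rowSums(sdir^2))
    spos <- 2 * sdir

    d2 <- outer(rowSums(spos^2), rowSums(vpos^2), "+") -
      2 * tcrossprod(spos, vpos)
    d2[d2 < 0] <- 0
    lead <- exp(-d2 / (2 * decay^2))

    structure(list(vertex_positions = vpos, vertex_hemi = hemi,
                   vertex_region = region, sensor_positions = spos,
                   lead_field = lead, decay = decay, seed = seed),
              class = "head_model")
  })
}

#' Select sensorimotor ROI vertices of one hemisphere
#'
#' @param head_model a [build_toy_head_model()] object.
#' @param hemisphere `"contra"` or `"ipsi"` (relative to the affected hand).
#' @return integer vertex ids.
#' @export
select_roi <- function(head_model, hemisphere = c("contra", "ipsi")) {
  stopifnot(inherits(head_model, "head_model"))
  hemisphere <- match.arg(hemisphere)
  ids <- which(head_model$vertex_hemi == hemisphere &
                 head_model$vertex_region == "sensorimotor")
  if (length(ids) == 0L)
    stop(sprintf("empty sensorimotor ROI in hemisphere '%s'", hemisphere),
         call. = FALSE)
  ids
}

#' Select sensors closest to the sensorimotor cortex
#'
#' Picks the `n` sensors nearest to the centroid of the sensorimotor ROI
#' (both hemispheres pooled). The toy default pipeline uses all sensors; this
#' selector exists for large sensor arrays where only a subset over the
#' sensorimotor cortex is carried downstream.
#'
#' @param head_model a [build_toy_head_model()] object.
#' @param n number of sensors to keep.
#' @return integer sensor indices, sorted.
#' @export
select_channels <- function(head_model, n = 84) {
  stopifnot(inherits(head_model, "head_model"))
  n <- assert_count(n, "n")
  if (n > nrow(head_model$sensor_positions))
    stop("`n` exceeds the number of sensors", call. = FALSE)
  roi <- which(head_model$vertex_region == "sensorimotor")
  centroid <- colMeans(head_model$vertex_positions[roi, , drop = FALSE])
  d <- sqrt(rowSums(sweep(head_model$sensor_positions, 2, centroid)^2))
  sort(order(d)[seq_len(n)])
}

#' Head-model presets
#'
#' `"toy"` is the desk-scale default (32 sensors, 40 vertices per hemisphere,
#' half of them sensorimotor). `"study"` reproduces the published scale:
#' 4,004 dipoles over both hemispheres, 126 sensorimotor vertices per
#' hemisphere and an 84-channel selection out of a 160-sensor array.
#'
#' @param preset `"toy"` or `"study"`.
#' @param seed integer seed.
#' @return a `head_model`; for `"study"` it carries a `selected_channels`
#'   attribute with the 84 chosen sensor indices.
#' @export
head_model_preset <- function(preset = c("toy", "study"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "toy")
    return(build_toy_head_model(32, 40, 0.5, seed = seed))
  hm <- build_toy_head_model(n_sensors = 160, n_vertices_per_hemi = 2002,
                             roi_fraction = 126 / 2002, seed = seed)
  attr(hm, "selected_channels") <- select_channels(hm, 84)
  hm
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> %d sensors, %d vertices (%d sensorimotor)\n",
              nrow(x$lead_field), ncol(x$lead_field),
              sum(x$vertex_region == "sensorimotor")))
  invisible(x)
}
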