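#' Spherical head conductor model
#'
#' @param center 3-vector, sphere center in meters.
#' @param radius Sphere radius in meters (> 0).
#' @return Object of class `head_model`.
#' @export
head_model <- function(center = c(0, 0, 0), radius = 0.09) {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "head_model")
}

#' Synthetic MEG sensor array
#'
#' Deterministic array of point magnetometers with radial (axial) sensitive
#' orientation, placed on a hemispherical cap by a Fibonacci lattice. This is
#' a reduced stand-in for a whole-head axial gradiometer system: positions
#' are reproducible, cover the upper hemisphere evenly and lie strictly
#' outside the conductor sphere.
#'
#' @param n_sensors Number of sensors (default 60).
#' @param radius Cap radius in meters (default 0.10; must exceed the head
#'   radius wherever the two are used together).
#' @param center Cap center (same as the head center normally).
#' @return Object of class `sensor_array`: list with `positions` and
#'   `orientations` (`n x 3` matrices) and `radius`.
#' @export
meg_sensor_array <- function(n_sensors = 60L, radius = 0.10,
                             center = c(0, 0, 0)) {
  stopifnot(n_sensors >= 8L, radius > 0)
  i <- seq_len(n_sensors) - 0.5
  golden <- pi * (3 - sqrt(5))
  # z from just above equator to pole: hemispherical cap
  z <- i / n_sensors            # in (0, 1)
  theta <- golden * (seq_len(n_sensors) - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(rho * cos(theta), rho * sin(theta), z)
  pos <- sweep(u * radius, 2, center, "+")
  structure(list(positions = pos, orientations = u, radius = radius,
                 center = as.numeric(center)),
            class = "sensor_array")
}

#' Posterior sensor subset used for sensor-level evoked analysis
#'
#' Indices of the five most posterior (most negative y) sensors of the
#' synthetic array, mirroring the fixed posterior-occipital sensor selection
#' used for sensor-space visual-evoked-field analysis.
#'
#' @param array A [meg_sensor_array()] object.
#' @param n Number of sensors to select (default 5).
#' @return Integer vector of sensor indices.
#' @export
posterior_sensors <- function(array, n = 5L) {
  order(array$positions[, 2])[seq_len(n)]
}

#' Regular source grid inside the head sphere
#'
#' Builds a regular isotropic grid over the sphere's bounding box, marks which
#' locations lie inside the conductor, and marks an anatomical search mask.
#' In the synthetic geometry the "visual cortex" search region is the
#' posterior part of the sphere (y below `mask_y_max`), standing in for the
#' calcarine/cuneus/lingual mask of an atlas-based analysis.
#'
#' @param head A [head_model()].
#' @param spacing Grid spacing in meters (default 0.005, i.e. 5 mm).
#' @param interior_margin Margin (m) inside the sphere surface for the
#'   inside mask; sources too close to the surface are excluded.
#' @param mask_y_max Anatomical mask: inside locations with
#'   `y <= mask_y_max` (relative to the head center) are searchable.
#' @return Object of class `source_grid`: list with `locations` (`n x 3`),
#'   `spacing`, `inside`, `mask` (logical vectors over all grid points).
#' @export
source_grid <- function(head, spacing = 0.005, interior_margin = 0.015,
                        mask_y_max = -0.02) {
  stopifnot(inherits(head, "head_model"), spacing > 0)
  r <- head$radius
  ax <- seq(-r, r, by = spacing)
  locs <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  locs <- sweep(locs, 2, head$center, "+")
  rel <- sweep(locs, 2, head$center)
  d <- sqrt(rowSums(rel^2))
  inside <- d < (r - interior_margin)
  mask <- inside & rel[, 2] <= mask_y_max
  if (!any(mask)) abort("anatomical mask is empty; relax mask_y_max")
  structure(list(locations = locs, spacing = spacing,
                 inside = inside, mask = mask, head = head),
            class = "source_grid")
}

#' Regular source grid over a rectangular region of interest
#'
#' Dense grid restricted to a box (e.g. a small occipital search region),
#' useful for fine-spacing localization studies where scanning the whole
#' sphere interior is unnecessary. All in-box, in-sphere locations form both
#' the inside set and the anatomical mask.
#'
#' @param head A [head_model()].
#' @param center Box center (m).
#' @param half_extent Half side length(s) of the box (m; scalar or
#'   3-vector).
#' @param spacing Grid spacing (m).
#' @return A `source_grid` object.
#' @export
source_grid_box <- function(head, center = head$center + c(0, -0.045, 0.01),
                            half_extent = 0.015, spacing = 0.005) {
  stopifnot(inherits(head, "head_model"), spacing > 0)
  he <- rep(half_extent, length.out = 3)
  axes <- lapply(1:3, function(d) {
    seq(center[d] - he[d], center[d] + he[d], by = spacing)
  })
  locs <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  rel <- sweep(locs, 2, head$center)
  inside <- sqrt(rowSums(rel^2)) < head$radius - 0.005
  if (!any(inside)) abort("box lies outside the conductor sphere")
  structure(list(locations = locs, spacing = spacing,
                 inside = inside, mask = inside, head = head),
            class = "source_grid")
}
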