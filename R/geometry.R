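#' Fan-beam scanner geometry
#'
#' Describes a flat (equidistant) detector fan-beam CT scanner rotating around
#' the isocenter. World coordinates are in mm with the isocenter at the origin,
#' x to the right and y up. The view angle is the source azimuth measured
#' counter-clockwise from +y; by default the view angles cover a full turn,
#' `beta_k = 2*pi*k/N`, `k = 0..N-1`. Detector sample `k` (0-based) sits at
#' lateral offset `u_k = (k - (D-1)/2) * det_pitch` on a detector line at
#' distance `source_to_det` from the source, perpendicular to the central ray.
#'
#' @param source_to_iso Source-to-isocenter distance (mm).
#' @param source_to_det Source-to-detector distance (mm); must exceed
#'   `source_to_iso`.
#' @param n_detectors Number of detector cells.
#' @param det_pitch Detector cell pitch (mm).
#' @param n_views Number of projection views over a full turn; ignored when
#'   `view_angles` is given.
#' @param view_angles Optional explicit vector of view angles (radians).
#' @return An object of class `fanbeam_geometry`.
#' @export
fanbeam_geometry <- function(source_to_iso, source_to_det, n_detectors,
                             det_pitch, n_views = NULL, view_angles = NULL) {
  if (is.null(view_angles)) {
    if (is.null(n_views)) stop("give either n_views or view_angles")
    view_angles <- 2 * pi * (seq_len(n_views) - 1) / n_views
  }
  stopifnot(source_to_det > source_to_iso, source_to_iso > 0,
            length(view_angles) >= 1, det_pitch > 0, n_detectors >= 1)
  structure(list(
    source_to_iso = source_to_iso,
    source_to_det = source_to_det,
    n_detectors = as.integer(n_detectors),
    det_pitch = det_pitch,
    view_angles = as.numeric(view_angles),
    detector_shape = "flat_equidistant"
  ), class = "fanbeam_geometry")
}

#' @export
print.fanbeam_geometry <- function(x, ...) {
  cat(sprintf(
    "<fanbeam_geometry> SID %.1f mm, SDD %.1f mm, %d detectors @ %.3f mm, %d views\n",
    x$source_to_iso, x$source_to_det, x$n_detectors, x$det_pitch,
    length(x$view_angles)))
  invisible(x)
}

#' Number of views
#' @param geom A `fanbeam_geometry`.
#' @return Integer view count.
#' @export
n_views <- function(geom) length(geom$view_angles)

#' Lateral detector sample offsets
#' @param geom A `fanbeam_geometry`.
#' @return Numeric vector `u_k` (mm), centered on the central ray.
#' @export
detector_offsets <- function(geom) {
  (seq_len(geom$n_detectors) - 1 - (geom$n_detectors - 1) / 2) * geom$det_pitch
}

#' Source positions for all views
#' @param geom A `fanbeam_geometry`.
#' @return A `n_views x 2` matrix of world (x, y) source positions (mm).
#' @export
source_positions <- function(geom) {
  b <- geom$view_angles
  cbind(x = -geom$source_to_iso * sin(b), y = geom$source_to_iso * cos(b))
}

#' Project a world point onto the detector for every view
#'
#' Closed-form fan-beam point projection: the continuous (0-based) detector
#' index where the ray from the source through `point` crosses the detector,
#' for each view angle.
#'
#' @param point Numeric length-2 world coordinate (mm).
#' @param geom A `fanbeam_geometry`.
#' @return Numeric vector (one entry per view) of continuous detector indices.
#' @export
project_point_index <- function(point, geom) {
  stopifnot(length(point) == 2, all(is.finite(point)))
  b <- geom$view_angles
  sx <- -geom$source_to_iso * sin(b); sy <- geom$source_to_iso * cos(b)
  dx <- point[1] - sx; dy <- point[2] - sy
  tt <- dx * sin(b) + dy * (-cos(b))
  uu <- dx * cos(b) + dy * sin(b)
  if (any(tt <= 0)) stop("point lies behind (or at) the source for some view")
  (geom$source_to_det * uu / tt) / geom$det_pitch + (geom$n_detectors - 1) / 2
}

#' Geometry after detector binning
#' @param geom A `fanbeam_geometry`.
#' @param s Integer binning scale; must divide `n_detectors`.
#' @return A `fanbeam_geometry` with `n_detectors/s` cells of pitch
#'   `det_pitch*s`. Cell centers remain center-aligned with the original grid.
#' @export
bin_geometry <- function(geom, s) {
  s <- as.integer(s)
  if (s < 1) stop("binning scale must be >= 1")
  if (geom$n_detectors %% s != 0) stop("detector count not divisible by s")
  fanbeam_geometry(geom$source_to_iso, geom$source_to_det,
                   geom$n_detectors %/% s, geom$det_pitch * s,
                   view_angles = geom$view_angles)
}
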