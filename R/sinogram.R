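#' Sinogram container
#'
#' A `views x detectors` matrix of fan-beam line integrals together with its
#' geometry, processing stage and detector binning scale. The stage advances
#' only forward: `raw` (line integrals p) -> `cos_weighted` -> `filtered`
#' (the z of the FBP chain).
#'
#' @param data Numeric `N x D` matrix.
#' @param geometry A `fanbeam_geometry` with `N` views and `D` detectors.
#' @param stage One of `"raw"`, `"cos_weighted"`, `"filtered"`.
#' @param s Detector binning scale recorded for provenance (default 1).
#' @param meta Optional list of extra metadata.
#' @return A `sinogram` object.
#' @export
sinogram <- function(data, geometry, stage = "raw", s = 1L, meta = list()) {
  stopifnot(inherits(geometry, "fanbeam_geometry"),
            nrow(data) == n_views(geometry),
            ncol(data) == geometry$n_detectors,
            stage %in% c("raw", "cos_weighted", "filtered"))
  structure(list(data = data, geometry = geometry, stage = stage,
                 s = as.integer(s), meta = meta), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d detectors, stage=%s, s=%d\n",
              nrow(x$data), ncol(x$data), x$stage, x$s))
  invisible(x)
}

#' Fan-beam forward projection
#'
#' Ray-driven line integrals of the attenuation map along the rays from the
#' source to each detector cell center, marched at a fixed step of
#' `step_frac` pixels with bilinear sampling. A phantom (HU) is converted to
#' attenuation with [hu_to_mu()]; a plain matrix is taken to be attenuation
#' in 1/mm already.
#'
#' @param object A `phantom`, or a numeric matrix of attenuation values, or a
#'   `recon_image`.
#' @param geometry A `fanbeam_geometry`.
#' @param pixel_spacing Pixel size in mm (taken from the object if it carries
#'   one).
#' @param mu_water Water attenuation used for the HU conversion (1/mm).
#' @param step_frac Ray-march step as a fraction of the pixel size (<= 0.25
#'   by default).
#' @return A `raw`-stage [sinogram()] of line integrals (dimensionless,
#'   mu * mm). If the object support may exceed the detector field of view a
#'   warning is raised and `meta$truncated` is set.
#' @export
forward_project <- function(object, geometry, pixel_spacing = NULL,
                            mu_water = 0.02, step_frac = 0.25) {
  if (inherits(object, "phantom")) {
    img <- hu_to_mu(object$values, mu_water)
    pixel_spacing <- object$pixel_spacing
  } else if (inherits(object, "recon_image")) {
    img <- object$data
    pixel_spacing <- object$pixel_spacing
  } else {
    img <- object
    if (is.null(pixel_spacing)) stop("pixel_spacing required for bare matrices")
  }
  stopifnot(is.matrix(img), step_frac > 0)

  # conservative field-of-view check on the grid's bounding circle
  r_sup <- 0.5 * sqrt(2) * nrow(img) * pixel_spacing
  truncated <- FALSE
  if (r_sup < geometry$source_to_iso) {
    u_need <- geometry$source_to_det * tan(asin(r_sup / geometry$source_to_iso))
    u_have <- (geometry$n_detectors / 2) * geometry$det_pitch
    if (u_need > u_have) {
      warning("object bounding circle may exceed the detector field of view; ",
              "rays may be truncated")
      truncated <- TRUE
    }
  }

  p <- cpp_forward_project(img, pixel_spacing, geometry$view_angles,
                           geometry$source_to_iso, geometry$source_to_det,
                           geometry$det_pitch, geometry$n_detectors, step_frac)
  sinogram(p, geometry, stage = "raw",
           meta = list(truncated = truncated, mu_water = mu_water))
}

#' Poisson counting noise on line integrals
#'
#' Simulates a transmission measurement with `photons_i0` incident photons:
#' counts are drawn as `Poisson(I0 * exp(-p))` and converted back to noisy
#' line integrals `p' = -log(max(counts, 1) / I0)`; zero counts are clipped
#' to one photon before the log (recorded in `meta$zero_count_clip`).
#'
#' @param sino A `raw`-stage [sinogram()] with non-negative line integrals.
#' @param photons_i0 Incident photon count per ray (> 0). Default 1e6.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `raw`-stage sinogram of noisy line integrals.
#' @export
add_poisson_noise <- function(sino, photons_i0 = 1e6, seed = 0L) {
  stopifnot(inherits(sino, "sinogram"), sino$stage == "raw", photons_i0 > 0)
  if (any(sino$data < 0)) stop("negative line integrals")
  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  lam <- photons_i0 * exp(-sino$data)
  counts <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
  nclip <- sum(counts == 0)
  p <- -log(pmax(counts, 1) / photons_i0)
  out <- sino
  out$data <- p
  out$meta$photons_i0 <- photons_i0
  out$meta$noise_seed <- seed
  out$meta$zero_count_clip <- nclip
  out
}

#' Detector binning
#'
#' Averages groups of `s` adjacent detector cells (arithmetic mean, so
#' line-integral magnitudes are unchanged in scale) and updates the geometry:
#' `D/s` cells of pitch `s * det_pitch`, still center-aligned.
#'
#' @param sino A [sinogram()] at any stage (binning is normally applied to
#'   raw data before filtering).
#' @param s Integer scale; must divide the detector count.
#' @return The binned sinogram with `$s` multiplied by `s`.
#' @export
bin_detector <- function(sino, s) {
  stopifnot(inherits(sino, "sinogram"))
  s <- as.integer(s)
  if (s == 1L) return(sino)
  D <- ncol(sino$data)
  if (D %% s != 0) stop("detector count not divisible by s")
  grp <- rep(seq_len(D %/% s), each = s)
  binned <- t(rowsum(t(sino$data), grp, reorder = FALSE)) / s
  sinogram(binned, bin_geometry(sino$geometry, s), stage = sino$stage,
           s = sino$s * s, meta = c(sino$meta, list(binned_by = s)))
}

#' Write / read a sinogram container
#'
#' Serializes the sinogram matrix and its geometry/stage/binning metadata as a
#' single self-describing container file.
#'
#' @param sino A [sinogram()].
#' @param path Output file path.
#' @return `write_sinogram` returns `path` invisibly; `read_sinogram` the
#'   restored `sinogram`.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  saveRDS(sino, path)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "sinogram"))
  x
}
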