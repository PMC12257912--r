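#' Reconstructed image container
#'
#' @param data Numeric `H x W` matrix (attenuation in 1/mm unless noted).
#' @param pixel_spacing Pixel size (mm).
#' @param origin World (x, y) of the center of pixel (1, 1) (top-left row,
#'   +y up).
#' @param roi Optional [roi_spec()] provenance.
#' @param meta Optional metadata list.
#' @return A `recon_image`.
#' @export
recon_image <- function(data, pixel_spacing, origin, roi = NULL, meta = list()) {
  stopifnot(is.matrix(data), pixel_spacing > 0, length(origin) == 2)
  structure(list(data = data, pixel_spacing = pixel_spacing,
                 origin = as.numeric(origin), roi = roi, meta = meta),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %dx%d @ %.4g mm, origin (%.2f, %.2f)\n",
              nrow(x$data), ncol(x$data), x$pixel_spacing,
              x$origin[1], x$origin[2]))
  invisible(x)
}

# grid spec for a centered square reconstruction
full_grid <- function(grid_size, pixel_spacing) {
  half <- (grid_size - 1) / 2 * pixel_spacing
  list(H = grid_size, W = grid_size, spacing = pixel_spacing,
       ox = -half, oy = half)
}

roi_grid <- function(roi) {
  sp <- roi$patch_extent / roi$out_resolution
  half <- (roi$out_resolution - 1) / 2 * sp
  list(H = roi$out_resolution, W = roi$out_resolution, spacing = sp,
       ox = roi$center[1] - half, oy = roi$center[2] + half)
}

#' Cosine weighting for flat-detector fan-beam data
#'
#' Multiplies each detector sample by the cosine of its fan angle relative to
#' the central ray, `w(u) = SDD / sqrt(SDD^2 + u^2)` with `u` the lateral
#' detector offset: the first step of the FBP chain.
#'
#' @param sino A `raw`-stage [sinogram()].
#' @return The sinogram advanced to stage `cos_weighted`.
#' @export
cosine_weight <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  if (sino$stage != "raw") stop("cosine_weight expects a raw-stage sinogram")
  u <- detector_offsets(sino$geometry)
  w <- sino$geometry$source_to_det / sqrt(sino$geometry$source_to_det^2 + u^2)
  out <- sino
  out$data <- sweep(sino$data, 2, w, `*`)
  out$stage <- "cos_weighted"
  out
}

# band-limited ramp kernel value at signed integer lag, sampling interval dl
ramp_kernel <- function(lags, dl) {
  h <- numeric(length(lags))
  h[lags == 0] <- 1 / (4 * dl^2)
  odd <- lags %% 2 != 0
  h[odd] <- -1 / (pi * lags[odd] * dl)^2
  h
}

#' Ramp filtering of a cosine-weighted sinogram
#'
#' Per-view 1D convolution with the band-limited (Ram-Lak) ramp kernel
#' `h[0] = 1/(4 dl^2)`, `h[k] = -1/(pi k dl)^2` for odd `k`, 0 for even `k`,
#' where `dl` is the detector pitch scaled to the isocenter
#' (`det_pitch * SID/SDD`). Evaluated by FFT with zero-padding to the next
#' power of two >= 2D to suppress wrap-around; the result is multiplied by
#' `dl` (discrete approximation of the continuous filtering integral). The
#' optional Hann window apodizes the ramp response up to Nyquist.
#'
#' @param sino A `cos_weighted`-stage [sinogram()].
#' @param window `"ramlak"` (default) or `"hann"`.
#' @return The filtered sinogram (stage `filtered`, the z of the FBP chain).
#' @export
ramp_filter <- function(sino, window = c("ramlak", "hann")) {
  stopifnot(inherits(sino, "sinogram"))
  if (sino$stage != "cos_weighted")
    stop("ramp_filter expects a cos_weighted-stage sinogram")
  window <- match.arg(window)
  D <- ncol(sino$data)
  dl <- sino$geometry$det_pitch *
    sino$geometry$source_to_iso / sino$geometry$source_to_det
  P <- 2^ceiling(log2(2 * D))
  lags <- c(0:(P / 2), seq(-P / 2 + 1, -1))  # wrap-around lag ordering
  H <- Re(stats::fft(ramp_kernel(lags, dl)))
  if (window == "hann") {
    j <- 0:(P - 1)
    fsigned <- ifelse(j <= P / 2, j, j - P)
    H <- H * 0.5 * (1 + cos(pi * abs(fsigned) / (P / 2)))
  }
  zpad <- matrix(0, nrow(sino$data), P)
  zpad[, seq_len(D)] <- sino$data
  # FFT rows: mvfft works on columns, so transpose
  Zf <- stats::mvfft(t(zpad))
  filt <- Re(stats::mvfft(Zf * H, inverse = TRUE)) / P
  out <- sino
  out$data <- t(filt)[, seq_len(D), drop = FALSE] * dl
  out$stage <- "filtered"
  out$meta$filter_window <- window
  out
}

#' Fan-beam filtered back-projection
#'
#' Back-projects a filtered sinogram onto a pixel grid with cross-weighted
#' linear interpolation between the two detector samples bracketing each
#' pixel's projected coordinate (the nearer sample weighted by the distance to
#' the farther one), the inverse-square source-to-pixel magnification weight
#' `1/L_iq^2`, and angular/overscan scaling `pi/N * SID^2` for a full-turn
#' scan, so values approximate attenuation in 1/mm.
#'
#' Pixels whose projected coordinate falls outside the detector for some view
#' receive no contribution from that view; the per-pixel count of such views
#' is returned in `meta$n_outside`.
#'
#' @param z A `filtered`-stage [sinogram()].
#' @param grid_size Output grid side length (pixels) for a centered square
#'   reconstruction, or `NULL` when `roi` is given.
#' @param pixel_spacing Output pixel size (mm).
#' @param roi Optional [roi_spec()]: reconstruct that patch instead of a
#'   centered grid.
#' @return A [recon_image()] in 1/mm.
#' @export
backproject_fbp <- function(z, grid_size = NULL, pixel_spacing = NULL,
                            roi = NULL) {
  stopifnot(inherits(z, "sinogram"))
  if (z$stage != "filtered") stop("backproject_fbp expects a filtered sinogram")
  g <- if (!is.null(roi)) roi_grid(roi) else {
    stopifnot(!is.null(grid_size), !is.null(pixel_spacing))
    full_grid(grid_size, pixel_spacing)
  }
  res <- cpp_backproject_fbp(z$data, z$geometry$view_angles,
                             z$geometry$source_to_iso, z$geometry$source_to_det,
                             z$geometry$det_pitch, g$H, g$W, g$spacing,
                             g$ox, g$oy)
  recon_image(res$image, g$spacing, c(g$ox, g$oy), roi = roi,
              meta = list(n_outside = res$n_outside))
}

#' Full FBP chain
#'
#' Convenience wrapper: cosine weighting, ramp filtering and back-projection
#' of a raw sinogram.
#'
#' @inheritParams backproject_fbp
#' @param sino A `raw`-stage [sinogram()].
#' @param window Ramp filter window, see [ramp_filter()].
#' @return A [recon_image()] in 1/mm.
#' @export
fbp <- function(sino, grid_size = NULL, pixel_spacing = NULL, roi = NULL,
                window = "ramlak") {
  backproject_fbp(ramp_filter(cosine_weight(sino), window = window),
                  grid_size, pixel_spacing, roi = roi)
}
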