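#' Write / read a phantom as TIFF + JSON sidecar
#'
#' The HU map is stored as float32 TIFF; spacing, ellipse table, lesion list
#' and seed go to `<path>.json`.
#'
#' @param phantom A `phantom`.
#' @param path TIFF file path.
#' @return `write_phantom` returns `path` invisibly; `read_phantom` the
#'   restored `phantom` (values at float32 precision).
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  sc <- write_float_tiff(phantom$values, path)
  side <- list(grid_size = phantom$grid_size,
               pixel_spacing = phantom$pixel_spacing,
               kind = phantom$kind, seed = phantom$seed,
               value_offset = sc$offset, value_scale = sc$scale,
               ellipses = phantom$ellipses, lesions = phantom$lesions)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  vals <- tiff::readTIFF(path, as.is = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- matrix(vals, nrow(vals), ncol(vals)) * side$value_scale +
    side$value_offset
  ell <- as.data.frame(side$ellipses)
  new_phantom(vals, side$grid_size,
              side$pixel_spacing, ell, side$kind, side$seed,
              lesions = if (is.null(side$lesions)) list() else side$lesions)
}

# TIFF stores [0, 1]; keep the affine normalization for the sidecar
write_float_tiff <- function(m, path) {
  lo <- min(m); hi <- max(m)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((m - lo) / scale, path, bits.per.sample = 32, reduce = FALSE)
  list(offset = lo, scale = scale)
}

#' Write a reconstructed image as normalized float32 TIFF
#'
#' Values are min-max normalized for storage; the affine scale is written to
#' `<path>.json`.
#'
#' @param image A [recon_image()] or numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recon <- function(image, path) {
  m <- if (inherits(image, "recon_image")) image$data else image
  sc <- write_float_tiff(m, path)
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
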