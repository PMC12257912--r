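#' Region-of-interest specification
#'
#' @param center World (x, y) mm of the patch center.
#' @param patch_extent Side length of the square patch in mm.
#' @param out_resolution Output pixels per side (>= 1); the patch can be
#'   rendered at any resolution, independent of the detector sampling.
#' @param s Detector binning scale the ROI will be reconstructed from.
#' @return An `roi_spec`.
#' @export
roi_spec <- function(center, patch_extent, out_resolution, s = 1L) {
  stopifnot(length(center) == 2, patch_extent > 0, out_resolution >= 1)
  structure(list(center = as.numeric(center), patch_extent = patch_extent,
                 out_resolution = as.integer(out_resolution),
                 s = as.integer(s)),
            class = "roi_spec")
}

# round half away from zero (the window centering rule; ordinary round()
# would round half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Detector index of the ROI center for every view
#'
#' Closed-form fan-beam point projection of the ROI center: for each view, the
#' real-valued detector index where the ray through the center hits the
#' detector. This is the trajectory around which the sinogram window is cut.
#'
#' @param roi An [roi_spec()].
#' @param geometry A `fanbeam_geometry` (at the binning scale the window will
#'   be cut from).
#' @return Numeric vector of continuous detector indices, one per view.
#' @export
roi_center_index <- function(roi, geometry) {
  project_point_index(roi$center, geometry)
}

#' Sinogram unfolding
#'
#' Stacks the 3x3 neighborhood of every filtered-sinogram sample as 9
#' channels: channel `c = 3*(i+1) + (j+1) + 1` (1-based) holds the sinogram
#' shifted by `i` views and `j` detector cells, `i, j` in -1..1; the center
#' channel (5) equals the input, borders are zero-filled. Contracting the 9
#' channels with 1x1 weights is then equivalent to a 3x3 convolution on the
#' unsqueezed sinogram, which is what preserves local context through
#' squeezing.
#'
#' @param z A `filtered`-stage [sinogram()].
#' @return The sinogram with `$data` replaced by an `N x D x 9` array and
#'   `$unfolded = TRUE`.
#' @export
unfold <- function(z) {
  stopifnot(inherits(z, "sinogram"))
  if (z$stage != "filtered") stop("unfold expects a filtered sinogram")
  N <- nrow(z$data); D <- ncol(z$data)
  out <- array(0, c(N, D, 9))
  for (i in -1:1) for (j in -1:1) {
    ch <- 3 * (i + 1) + (j + 1) + 1
    rows <- seq_len(N); cols <- seq_len(D)
    rok <- rows + i >= 1 & rows + i <= N
    cok <- cols + j >= 1 & cols + j <= D
    out[rows[rok], cols[cok], ch] <- z$data[rows[rok] + i, cols[cok] + j]
  }
  z$data9 <- out
  z$unfolded <- TRUE
  z
}

#' Sinogram squeezing
#'
#' Cuts, for every view, the detector window of width `d` centered on the
#' (rounded) ROI-center index and stacks the windows into a rectangular
#' `N x d` array (or `N x d x 9` for unfolded input). The detector axis is
#' conceptually zero-padded by `pad` cells on both sides first, so windows
#' may extend past the physical detector; the per-view integer offset of
#' window column 1 is recorded so any original detector coordinate maps to a
#' squeezed column and back without loss. Under the training protocol
#' `d = 64/s` and `pad = 256/s` at binning scale `s`.
#'
#' @param z A `filtered`-stage [sinogram()], optionally [unfold()]ed.
#' @param center_index Per-view real-valued center indices, e.g. from
#'   [roi_center_index()].
#' @param d Even window width (detector cells).
#' @param pad Zero-padding width (>= d/2) allowed on each side.
#' @return A `squeezed_sinogram`: `$data` (`N x d` or `N x d x 9`),
#'   `$win_off` (0-based original detector index of window column 1),
#'   `$center_index`, `$d`, `$pad`, `$unfolded`, plus the source geometry and
#'   binning scale.
#' @export
squeeze_sinogram <- function(z, center_index, d, pad) {
  stopifnot(inherits(z, "sinogram"))
  if (z$stage != "filtered") stop("squeeze expects a filtered sinogram")
  d <- as.integer(d); pad <- as.integer(pad)
  if (d %% 2 != 0) stop("window width d must be even")
  if (pad < d / 2) stop("pad must be at least d/2")
  N <- nrow(z$data); D <- ncol(z$data)
  stopifnot(length(center_index) == N, all(is.finite(center_index)))
  win_off <- as.integer(round_half_away(center_index)) - d %/% 2L
  if (any(win_off < -pad) || any(win_off + d - 1L > D - 1L + pad))
    stop("window exceeds the padded detector range: pad too small")
  unfolded <- isTRUE(z$unfolded)
  src <- if (unfolded) z$data9 else z$data
  nch <- if (unfolded) 9L else 1L
  out <- array(0, c(N, d, nch))
  for (i in seq_len(N)) {
    idx <- win_off[i] + 0:(d - 1L)          # 0-based original indices
    ok <- idx >= 0L & idx <= D - 1L
    if (any(ok)) {
      if (unfolded) out[i, ok, ] <- src[i, idx[ok] + 1L, ]
      else out[i, ok, 1] <- src[i, idx[ok] + 1L]
    }
  }
  structure(list(
    data = if (unfolded) out else out[, , 1, drop = TRUE],
    win_off = win_off, center_index = center_index, d = d, pad = pad,
    unfolded = unfolded, geometry = z$geometry, s = z$s,
    stage = "filtered"), class = "squeezed_sinogram")
}

#' @export
print.squeezed_sinogram <- function(x, ...) {
  cat(sprintf("<squeezed_sinogram> %d views x %d cols%s, pad=%d, s=%d\n",
              length(x$win_off), x$d, if (x$unfolded) " x 9ch" else "",
              x$pad, x$s))
  invisible(x)
}

#' Undo squeezing (copy windows back)
#'
#' Writes the squeezed windows back into a zero `N x D` sinogram-shaped
#' matrix; values at covered detector indices are reproduced exactly.
#'
#' @param sq A `squeezed_sinogram` (single-channel).
#' @return An `N x D` matrix.
#' @export
unsqueeze_sinogram <- function(sq) {
  stopifnot(inherits(sq, "squeezed_sinogram"), !sq$unfolded)
  N <- length(sq$win_off); D <- sq$geometry$n_detectors
  out <- matrix(0, N, D)
  for (i in seq_len(N)) {
    idx <- sq$win_off[i] + 0:(sq$d - 1L)
    ok <- idx >= 0L & idx <= D - 1L
    out[i, idx[ok] + 1L] <- sq$data[i, ok]
  }
  out
}

#' Map an original detector coordinate into a squeezed window
#'
#' Affine index translation: squeezed column (0-based, fractional part
#' preserved) of the original continuous detector coordinate `x` in view `i`.
#'
#' @param x Continuous 0-based detector coordinate(s) in original units.
#' @param view View index (1-based), recycled against `x`.
#' @param sq A `squeezed_sinogram`.
#' @return Continuous 0-based squeezed column coordinate(s).
#' @export
map_ray_to_squeezed <- function(x, view, sq) {
  stopifnot(inherits(sq, "squeezed_sinogram"))
  col <- x - sq$win_off[view]
  bad <- col < 0 | col > sq$d - 1
  if (any(bad)) {
    v <- if (length(view) == 1) view else view[which(bad)[1]]
    stop("ray falls outside the squeezed window (insufficient d) at view ", v)
  }
  col
}

#' Inverse of [map_ray_to_squeezed()]
#' @param col Continuous squeezed column coordinate(s), 0-based.
#' @inheritParams map_ray_to_squeezed
#' @return Original continuous detector coordinate(s).
#' @export
map_squeezed_to_ray <- function(col, view, sq) col + sq$win_off[view]

#' Minimum window width for an ROI
#'
#' Estimates the smallest even `d` such that every ray through the patch maps
#' inside the squeezed window for all views: projects the four patch corners,
#' takes the maximum deviation from the center index over views, and adds the
#' rounding and interpolation margins.
#'
#' @param roi An [roi_spec()].
#' @param geometry A `fanbeam_geometry` at the target binning scale.
#' @return Even integer window width.
#' @export
min_window_width <- function(roi, geometry) {
  ci <- roi_center_index(roi, geometry)
  h <- roi$patch_extent / 2 * (roi$out_resolution - 1) / roi$out_resolution
  dev <- 0
  for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
    corner <- roi$center + h * c(sx, sy)
    dev <- max(dev, abs(project_point_index(corner, geometry) - ci))
  }
  2L * as.integer(ceiling(dev + 0.5 + 1)) + 2L
}
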