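#' Sinusoidal basis configuration
#'
#' The parameter-free decoder uses the orthonormal sinusoidal basis on
#' \[-1, 1\]: `e_1(x) = 1`, `e_{2k}(x) = sqrt(2) cos(k pi x)`,
#' `e_{2k+1}(x) = sqrt(2) sin(k pi x)` for `k = 1..n`, so the basis dimension
#' is `2n + 1` and `(1/2) * integral_{-1}^{1} e_i e_j dx = delta_ij`.
#'
#' @param n Maximum frequency index (>= 0). Default 5.
#' @return A `basis_config` with fields `n` and `dim = 2n + 1`.
#' @export
basis_config <- function(n = 5L) {
  n <- as.integer(n)
  stopifnot(n >= 0)
  structure(list(n = n, dim = 2L * n + 1L), class = "basis_config")
}

#' Positional encoding onto the sinusoidal basis
#'
#' @param x Normalized offset(s) in \[-1, 1\] (sub-detector-cell offsets in
#'   detector-pitch units).
#' @param n Maximum frequency index.
#' @return If `x` is scalar, a length `2n+1` vector
#'   `(1, sqrt2 cos(pi x), sqrt2 sin(pi x), ..., sqrt2 cos(n pi x),
#'   sqrt2 sin(n pi x))`; otherwise a `length(x) x (2n+1)` matrix.
#' @export
positional_encode <- function(x, n = 5L) {
  if (any(abs(x) > 1)) stop("|x| > 1: offsets must be normalized to [-1, 1]")
  n <- as.integer(n)
  out <- matrix(1, length(x), 2L * n + 1L)
  for (k in seq_len(n)) {
    out[, 2 * k] <- sqrt(2) * cos(k * pi * x)
    out[, 2 * k + 1] <- sqrt(2) * sin(k * pi * x)
  }
  if (length(x) == 1) drop(out) else out
}

#' Gram matrix of the sinusoidal basis
#'
#' `G[i, j] = (1/2) * integral_{-1}^{1} e_i(x) e_j(x) dx`, evaluated by
#' Gauss-Legendre quadrature. For any quadrature order >= 4(n+1) this is the
#' identity to machine precision: the orthonormality contract of the basis.
#'
#' @param n Maximum frequency index.
#' @param order Number of Gauss-Legendre nodes (default 256).
#' @return A `(2n+1) x (2n+1)` matrix.
#' @export
gram_matrix <- function(n = 5L, order = 256L) {
  stopifnot(order >= 4 * (n + 1))
  gl <- pracma::gaussLegendre(order, -1, 1)
  E <- positional_encode(gl$x, n)
  if (is.null(dim(E))) E <- matrix(E, nrow = length(gl$x))
  0.5 * t(E * gl$w) %*% E
}

#' Parameter-free sinusoidal decoding
#'
#' `f(z*, x) = z* . PE(x)`: inner product of a feature vector with the
#' positional encoding of the normalized offset. Linear in `z*`.
#'
#' @param z_star Numeric feature vector of length `2n+1`.
#' @param x Normalized offset in \[-1, 1\].
#' @param n Maximum frequency index; inferred from `length(z_star)` when
#'   omitted.
#' @return Scalar decoded value.
#' @export
decode <- function(z_star, x, n = NULL) {
  if (is.null(n)) {
    if (length(z_star) %% 2 != 1) stop("feature length must be odd (2n+1)")
    n <- (length(z_star) - 1L) %/% 2L
  }
  if (length(z_star) != 2 * n + 1) stop("feature/basis dimension mismatch")
  sum(z_star * positional_encode(x, n))
}

#' Per-view feature map aligned to a squeezed sinogram
#'
#' @param data Numeric `N x d x (2n+1)` array of decoder coefficients z*.
#' @param basis A [basis_config()].
#' @return A `basis_feature_map`.
#' @export
basis_feature_map <- function(data, basis = basis_config()) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == basis$dim,
            all(is.finite(data)))
  structure(list(data = data, basis = basis), class = "basis_feature_map")
}

#' Continuous-representation back-projection
#'
#' Back-projects a squeezed filtered sinogram onto an ROI grid of arbitrary
#' resolution, augmenting the cross-weighted linear interpolation of plain
#' FBP with the sinusoidal decoder: for each output pixel and view, with
#' bracketing squeezed samples `z_0, z_1`, interpolation weights
#' `l_0 = frac`, `l_1 = 1 - frac` (detector-pitch units) and normalized
#' offsets `D0 = frac` in \[0, 1\], `D1 = frac - 1` in \[-1, 0\], it
#' accumulates
#' `(1/L^2) * (l_0 * f(z*_1, D1) + l_1 * f(z*_0, D0) + l_0 * z_1 + l_1 * z_0)`.
#' With `features = NULL` (or all-zero coefficients) this reduces exactly to
#' plain FBP of the ROI. The operation is linear in the features; its adjoint
#' is available via [cret_backproject_grad()], so gradients flow through it.
#'
#' @param sq A `squeezed_sinogram` (single-channel filtered values; the
#'   unfolded 9-channel copy, when present, feeds the encoder, not this op).
#' @param roi An [roi_spec()].
#' @param features Optional [basis_feature_map()] (or bare `N x d x (2n+1)`
#'   array) aligned to `sq`.
#' @return A [recon_image()] in 1/mm with `meta$n_outside` counting, per
#'   pixel, the views whose ray fell outside the window.
#' @export
cret_backproject <- function(sq, roi, features = NULL) {
  stopifnot(inherits(sq, "squeezed_sinogram"), inherits(roi, "roi_spec"))
  zsq <- if (sq$unfolded) sq$data[, , 5] else sq$data
  g <- roi_grid(roi)
  nb <- 1L
  feat <- numeric(0)
  if (!is.null(features)) {
    fdata <- if (inherits(features, "basis_feature_map")) features$data else features
    stopifnot(length(dim(fdata)) == 3,
              dim(fdata)[1] == nrow(zsq), dim(fdata)[2] == ncol(zsq))
    nb <- dim(fdata)[3]
    if (nb %% 2 != 1) stop("feature channel count must be odd (2n+1)")
    feat <- as.numeric(fdata)
  }
  geom <- sq$geometry
  res <- cpp_cret_backproject(zsq, feat, nb, sq$win_off, geom$view_angles,
                              geom$source_to_iso, geom$source_to_det,
                              geom$det_pitch, geom$n_detectors,
                              g$H, g$W, g$spacing, g$ox, g$oy)
  recon_image(res$image, g$spacing, c(g$ox, g$oy), roi = roi,
              meta = list(n_outside = res$n_outside))
}

#' Gradient of [cret_backproject()] with respect to the features
#'
#' Adjoint of the (linear) features-to-image map: accumulates
#' `d(loss)/d(z*)` from `d(loss)/d(image)` under the identical ray sampling.
#'
#' @param grad_image Numeric `H x W` matrix of upstream gradients.
#' @param sq The `squeezed_sinogram` used in the forward call.
#' @param roi The [roi_spec()] used in the forward call.
#' @param nbasis Feature channel count `2n+1`.
#' @return Numeric `N x d x nbasis` gradient array.
#' @export
cret_backproject_grad <- function(grad_image, sq, roi, nbasis) {
  stopifnot(inherits(sq, "squeezed_sinogram"))
  g <- roi_grid(roi)
  geom <- sq$geometry
  d <- if (sq$unfolded) dim(sq$data)[2] else ncol(sq$data)
  cpp_cret_backproject_grad(grad_image, n_views(geom), d, as.integer(nbasis),
                            sq$win_off, geom$view_angles,
                            geom$source_to_iso, geom$source_to_det,
                            geom$det_pitch, geom$n_detectors,
                            g$spacing, g$ox, g$oy)
}

#' Normalized sub-cell offsets for every (pixel, view) pair
#'
#' Diagnostic companion to [cret_backproject()]: the normalized offsets
#' `D0 = x_iq - x_i0` and `D1 = x_iq - x_i1` (detector-pitch units) actually
#' used for each accumulated term, so their ranges (\[0, 1\] and \[-1, 0\])
#' can be asserted.
#'
#' @param sq A `squeezed_sinogram`.
#' @param roi An [roi_spec()].
#' @return List of `npix x nviews` matrices `d0`, `d1`, and logical `inside`.
#' @export
ray_offsets <- function(sq, roi) {
  g <- roi_grid(roi)
  geom <- sq$geometry
  xs <- g$ox + (seq_len(g$W) - 1) * g$spacing
  ys <- g$oy - (seq_len(g$H) - 1) * g$spacing
  pts <- cbind(x = rep(xs, each = g$H), y = rep(ys, times = g$W))
  nv <- n_views(geom)
  d0 <- d1 <- matrix(NA_real_, nrow(pts), nv)
  inside <- matrix(FALSE, nrow(pts), nv)
  dmax <- if (sq$unfolded) dim(sq$data)[2] else ncol(sq$data)
  for (q in seq_len(nrow(pts))) {
    t <- project_point_index(pts[q, ], geom)
    col <- t - sq$win_off
    k0 <- floor(col)
    ok <- k0 >= 0 & k0 + 1 <= dmax - 1
    inside[q, ] <- ok
    d0[q, ok] <- col[ok] - k0[ok]
    d1[q, ok] <- col[ok] - k0[ok] - 1
  }
  list(d0 = d0, d1 = d1, inside = inside)
}
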