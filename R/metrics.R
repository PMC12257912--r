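#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)`, symmetric in its arguments. Identical
#' images (MSE = 0) are reported as the capped sentinel 99 dB.
#'
#' @param a,b Numeric matrices of identical shape.
#' @param data_range Intensity span the peak refers to (e.g. the HU display
#'   span of the ground truth).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, data_range) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  stopifnot(data_range > 0)
  mse <- mean((a - b)^2)
  if (mse == 0) return(99)
  min(10 * log10(data_range^2 / mse), 99)
}

# normalized 2D Gaussian window (truncated at `radius` sigmas like the usual
# reference implementations: radius = round(truncate * sigma))
gaussian_window <- function(sigma = 1.5, truncate = 3.5) {
  r <- round(truncate * sigma)
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

filter2d <- function(x, w) {
  k <- dim(w)
  xa <- array(x, c(dim(x), 1L))
  wa <- array(w, c(k, 1L, 1L))
  matrix(cpp_conv2d_fw(xa, wa, 0), nrow(x), ncol(x))
}

#' Structural similarity index
#'
#' Windowed SSIM with the standard parameters: 2D Gaussian weights
#' (sigma 1.5, 11x11 window), K1 = 0.01, K2 = 0.03, Gaussian-weighted
#' (population) moments. The similarity map is averaged over the region
#' where the window fits entirely inside the image, so boundary handling
#' does not enter the score.
#'
#' @param a,b Numeric matrices of identical shape (each side > 2 * window
#'   radius).
#' @param data_range Intensity span of the data.
#' @param sigma Gaussian window standard deviation (pixels).
#' @param K1,K2 Stability constants.
#' @return SSIM score in \[-1, 1\].
#' @export
ssim <- function(a, b, data_range, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  stopifnot(data_range > 0)
  w <- gaussian_window(sigma)
  pad <- (nrow(w) - 1) / 2
  stopifnot(nrow(a) > 2 * pad, ncol(a) > 2 * pad)
  mu_a <- filter2d(a, w); mu_b <- filter2d(b, w)
  saa <- filter2d(a * a, w) - mu_a^2
  sbb <- filter2d(b * b, w) - mu_b^2
  sab <- filter2d(a * b, w) - mu_a * mu_b
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  S <- ((2 * mu_a * mu_b + C1) * (2 * sab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (saa + sbb + C2))
  rows <- (pad + 1):(nrow(a) - pad); cols <- (pad + 1):(ncol(a) - pad)
  mean(S[rows, cols])
}
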