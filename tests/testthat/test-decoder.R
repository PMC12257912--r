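# Positional encoding, orthonormality, decoding, and CRET back-projection.

test_that("positional encoding has the stated values and dimension", {
  expect_length(positional_encode(0.3, n = 5), 11)
  expect_equal(positional_encode(0, 1), c(1, sqrt(2), 0))
  expect_equal(positional_encode(0.5, 1), c(1, 0, sqrt(2)), tolerance = 1e-15)
  expect_equal(positional_encode(-1, 2), c(1, -sqrt(2), 0, sqrt(2), 0),
               tolerance = 1e-14)
  expect_equal(positional_encode(c(0, 0.5), 1),
               rbind(c(1, sqrt(2), 0), c(1, 0, sqrt(2))), tolerance = 1e-15)
  expect_error(positional_encode(1.2, 3), "normalized")
})

test_that("the basis is orthonormal under the half-interval inner product", {
  expect_equal(gram_matrix(0, 8), matrix(1), tolerance = 1e-15)
  G <- gram_matrix(5, 256)
  expect_equal(dim(G), c(11, 11))
  expect_lt(max(abs(G - diag(11))), 1e-12)
  # also at a different order and n
  G3 <- gram_matrix(3, 64)
  expect_lt(max(abs(G3 - diag(7))), 1e-12)
  expect_error(gram_matrix(5, 8))  # quadrature too coarse to certify
})

test_that("decoding is the inner product and is linear in the features", {
  e1 <- c(1, rep(0, 10))
  for (x in c(-1, -0.3, 0, 0.7)) expect_equal(decode(e1, x), 1)
  expect_equal(decode(rep(0, 11), 0.4), 0)
  set.seed(11)
  for (i in 1:20) {
    u <- rnorm(11); v <- rnorm(11); x <- runif(1, -1, 1)
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(decode(a * u + b * v, x),
                 a * decode(u, x) + b * decode(v, x), tolerance = 1e-12)
  }
  expect_error(decode(rnorm(10), 0.1), "odd")
  expect_error(decode(rnorm(11), 0.1, n = 3), "mismatch")
})

test_that("band-limited profiles are recovered exactly; excess bases add nothing", {
  # profile spanned by bases up to k = 3 on [-1, 1]
  f <- function(x) 0.4 - 1.1 * sqrt(2) * cos(pi * x) +
    0.7 * sqrt(2) * sin(2 * pi * x) + 0.25 * sqrt(2) * cos(3 * pi * x)
  gl <- pracma::gaussLegendre(128, -1, 1)
  xs <- seq(-1, 1, length.out = 201)
  err <- vapply(c(3, 5, 8), function(n) {
    # project f onto the basis with the half-interval inner product
    E <- positional_encode(gl$x, n)
    zstar <- 0.5 * as.numeric(t(E * gl$w) %*% f(gl$x))
    max(abs(vapply(xs, function(x) decode(zstar, x), numeric(1)) - f(xs)))
  }, numeric(1))
  expect_lt(err[1], 1e-12)              # n = 3 is already exact
  expect_lt(err[2], 1e-12)              # n = 5 cannot improve on exact
  expect_lt(abs(err[3] - err[2]), 1e-12)  # no error reduction beyond the band
})

test_that("zero features reduce CRET back-projection to plain FBP", {
  cfg <- mini_cfg(nv = 40)
  ph <- make_phantom("random_ellipses", cfg$grid_size, cfg$pixel_spacing, 2)
  smp <- prepare_sample(ph, c(57, 49), s = 1L, cfg, seed = 3, patch_px = 16L)
  z0 <- array(0, c(dim(smp$sq$data)[1:2], 11))
  with0 <- cret_backproject(smp$sq, smp$roi, z0)
  expect_lt(max(abs(with0$data - smp$y_fbp)), 1e-12)
  # and the features enter linearly
  set.seed(8)
  za <- array(rnorm(prod(dim(z0)), 0, 1e-5), dim(z0))
  zb <- array(rnorm(prod(dim(z0)), 0, 1e-5), dim(z0))
  ra <- cret_backproject(smp$sq, smp$roi, za)$data - smp$y_fbp
  rb <- cret_backproject(smp$sq, smp$roi, zb)$data - smp$y_fbp
  rab <- cret_backproject(smp$sq, smp$roi, 2 * za - zb)$data - smp$y_fbp
  expect_equal(rab, 2 * ra - rb, tolerance = 1e-10)
})

test_that("the reconstruction grid is resolution-agnostic", {
  cfg <- mini_cfg(nv = 40)
  ph <- make_phantom("random_ellipses", cfg$grid_size, cfg$pixel_spacing, 2)
  smp <- prepare_sample(ph, c(57, 49), s = 2L, cfg, seed = 3, patch_px = 16L)
  coarse <- cret_backproject(smp$sq, smp$roi, NULL)
  fine_roi <- smp$roi; fine_roi$out_resolution <- 48L  # 3x upsampling
  fine <- cret_backproject(smp$sq, fine_roi, NULL)
  # odd upsampling factor: fine pixel 3i+2 (1-based) shares the center of
  # coarse pixel i+1
  shared <- seq(2, 48, by = 3)
  expect_equal(fine$data[shared, shared], coarse$data, tolerance = 1e-9)
})

test_that("vectorized CRET matches a literal per-pixel per-view loop", {
  cfg <- mini_cfg(nv = 30)
  ph <- make_phantom("random_ellipses", cfg$grid_size, cfg$pixel_spacing, 4)
  smp <- prepare_sample(ph, c(49, 41), s = 2L, cfg, seed = 9, patch_px = 12L)
  set.seed(10)
  dims <- c(dim(smp$sq$data)[1:2], 7)  # n = 3 basis
  zstar <- array(rnorm(prod(dims), 0, 1e-5), dims)
  fast <- cret_backproject(smp$sq, smp$roi, zstar)$data

  geom <- smp$sq$geometry
  nv <- n_views(geom)
  pe <- function(x, n) {
    out <- 1
    for (k in 1:n) out <- c(out, sqrt(2) * cos(k * pi * x),
                            sqrt(2) * sin(k * pi * x))
    out
  }
  slow <- matrix(0, 12, 12)
  sp <- smp$roi$patch_extent / 12
  for (r in 1:12) for (c in 1:12) {
    px <- smp$roi$center[1] + (c - 6.5) * sp
    py <- smp$roi$center[2] + (6.5 - r) * sp
    acc <- 0
    for (i in 1:nv) {
      beta <- geom$view_angles[i]
      sx <- -600 * sin(beta); sy <- 600 * cos(beta)
      tt <- (px - sx) * sin(beta) + (py - sy) * (-cos(beta))
      uu <- (px - sx) * cos(beta) + (py - sy) * sin(beta)
      L2 <- (px - sx)^2 + (py - sy)^2
      t_idx <- (1000 * uu / tt) / geom$det_pitch + (geom$n_detectors - 1) / 2
      col <- t_idx - smp$sq$win_off[i]
      k0 <- floor(col); f <- col - k0
      z0 <- smp$sq$data[i, k0 + 1, 5]; z1 <- smp$sq$data[i, k0 + 2, 5]
      f0 <- sum(zstar[i, k0 + 1, ] * pe(f, 3))
      f1 <- sum(zstar[i, k0 + 2, ] * pe(f - 1, 3))
      acc <- acc + (f * f1 + (1 - f) * f0 + f * z1 + (1 - f) * z0) / L2
    }
    slow[r, c] <- acc * pi / nv * 600^2
  }
  expect_lt(max(abs(fast - slow)), 1e-8)
})
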