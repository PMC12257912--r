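# Cosine weighting, ramp filtering, back-projection, and the full FBP chain.

test_that("cosine weighting follows the flat-detector fan angle", {
  g <- tiny_geom(nv = 3)
  sino <- sinogram(matrix(1, 3, 128), g)
  w <- cosine_weight(sino)
  expect_equal(w$stage, "cos_weighted")
  u <- detector_offsets(g)
  central <- which.min(abs(u))
  expect_equal(w$data[1, central], 1000 / sqrt(1000^2 + u[central]^2))
  expect_equal(w$data[2, ], rev(w$data[2, ]))             # even in u
  expect_true(all(diff(w$data[1, u >= 0]) < 0))           # decreasing in |u|
  expect_error(cosine_weight(w), "raw")
})

test_that("ramp filter matches direct spatial convolution and kills DC", {
  g <- tiny_geom(nv = 2, ndet = 100)
  dl <- 3.2 * 600 / 1000
  imp <- matrix(0, 2, 100); imp[, 41] <- 1
  sino <- sinogram(imp, g, stage = "cos_weighted")
  z <- ramp_filter(sino)
  expect_equal(z$stage, "filtered")
  # oracle: direct convolution with the Ram-Lak kernel, z[k] = dl * h[k - k0]
  lag <- (1:100) - 41
  h <- numeric(100)
  h[lag == 0] <- 1 / (4 * dl^2)
  h[lag %% 2 != 0] <- -1 / (pi * lag[lag %% 2 != 0] * dl)^2
  expect_lt(max(abs(z$data[1, ] - dl * h)), 1e-10)

  # zero-frequency gain ~ 0: away from the support edges of the padded row,
  # the truncated kernel sums to O(1/D) of its peak
  gwide <- tiny_geom(nv = 1, ndet = 512)
  const <- ramp_filter(sinogram(matrix(1, 1, 512), gwide,
                                stage = "cos_weighted"))
  expect_lt(max(abs(const$data[, 129:384])), 1e-3)

  # linearity
  set.seed(4)
  a <- matrix(rnorm(200), 2); b <- matrix(rnorm(200), 2)
  fa <- ramp_filter(sinogram(a, g, stage = "cos_weighted"))$data
  fb <- ramp_filter(sinogram(b, g, stage = "cos_weighted"))$data
  fab <- ramp_filter(sinogram(2 * a - 3 * b, g, stage = "cos_weighted"))$data
  expect_equal(fab, 2 * fa - 3 * fb, tolerance = 1e-12)
  expect_error(ramp_filter(sinogram(a, g)), "cos_weighted")

  # the Hann window only attenuates: same DC suppression, smaller peak
  zh <- ramp_filter(sino, window = "hann")
  expect_lt(max(abs(zh$data)), max(abs(z$data)))
})

test_that("back-projection is linear and zero maps to zero", {
  g <- tiny_geom(nv = 30)
  z0 <- sinogram(matrix(0, 30, 128), g, stage = "filtered")
  expect_true(all(backproject_fbp(z0, 32, 2.0)$data == 0))
  set.seed(5)
  a <- random_filtered_sinogram(g, 5)
  b <- random_filtered_sinogram(g, 6)
  ra <- backproject_fbp(a, 32, 2.0)$data
  rb <- backproject_fbp(b, 32, 2.0)$data
  ab <- a; ab$data <- 3 * a$data - 0.5 * b$data
  expect_equal(backproject_fbp(ab, 32, 2.0)$data, 3 * ra - 0.5 * rb,
               tolerance = 1e-12)
  expect_error(backproject_fbp(sinogram(a$data, g), 32, 2.0), "filtered")
})

test_that("a single view back-projects as 1/L^2 along the fan", {
  g <- fanbeam_geometry(600, 1000, 128, 3.2, n_views = 1)
  z <- sinogram(matrix(0.5, 1, 128), g, stage = "filtered")
  rec <- backproject_fbp(z, 24, 2.0)
  # L^2 = squared distance from the source (0, 600) to each pixel
  xs <- (0:23 - 11.5) * 2.0
  L2 <- outer((rev(xs) - 600)^2, xs^2, "+")
  expect_equal(rec$data * L2 / (pi * 600^2 * 0.5), matrix(1, 24, 24),
               tolerance = 1e-12)
})

test_that("interpolation uses the cross-index convention (l_i0 weights z_i1)", {
  g <- fanbeam_geometry(600, 1000, 128, 3.2, n_views = 1)
  pt <- c(17.3, -24.9)
  t <- project_point_index(pt, g)
  k0 <- floor(t); frac <- t - k0
  expect_gt(frac, 0.05); expect_lt(frac, 0.95)  # genuinely between samples
  L2 <- sum((pt - c(0, 600))^2)
  grid1 <- function(zrow) {
    z <- sinogram(matrix(zrow, 1), g, stage = "filtered")
    # 1x1 grid centered exactly on the point
    roi <- roi_spec(pt, patch_extent = 1, out_resolution = 1)
    backproject_fbp(z, roi = roi)$data[1, 1]
  }
  scale <- pi * 600^2 / L2
  zrow <- numeric(128); zrow[k0 + 2] <- 1      # impulse at index k1 = k0 + 1
  expect_equal(grid1(zrow), scale * frac, tolerance = 1e-9)
  zrow <- numeric(128); zrow[k0 + 1] <- 1      # impulse at index k0
  expect_equal(grid1(zrow), scale * (1 - frac), tolerance = 1e-9)
})

test_that("reconstruction RMSE improves with views and rotates with the object", {
  ph <- make_phantom("shepp_logan", 64, 2.0, 0)
  g <- fanbeam_geometry(600, 1000, 256, 1.6, n_views = 180)
  sino <- forward_project(ph, g)
  mask <- interior_mask(ph)
  rmse <- function(nv) {
    keep <- seq(1, 180, by = 180 %/% nv)
    sub <- sinogram(sino$data[keep, ],
                    fanbeam_geometry(600, 1000, 256, 1.6,
                                     view_angles = g$view_angles[keep]),
                    stage = "raw")
    rec <- fbp(sub, 64, 2.0)
    sqrt(mean((mu_to_hu(rec$data) - ph$values)[mask]^2))
  }
  errs <- vapply(c(45, 90, 180), rmse, numeric(1))
  expect_true(all(diff(errs) < 0))  # strictly decreasing with view count

  # rotating the phantom by 90 deg rotates the reconstruction
  rot <- ph
  rot$ellipses <- transform(ph$ellipses, x0 = -y0, y0 = x0,
                            angle = angle + pi / 2)
  gpix <- phantom_grid(rot)
  grid <- expand.grid(y = gpix$y, x = gpix$x)
  rot$values <- matrix(cret:::eval_ellipses_hu(rot$ellipses, grid$x, grid$y),
                       64, 64)
  rot_ccw <- function(m) t(m)[nrow(m):1, ]
  expect_equal(rot$values, rot_ccw(ph$values))  # grid-exact rotation
  rec1 <- fbp(sinogram(sino$data, g), 64, 2.0)$data
  rec2 <- fbp(forward_project(rot, g), 64, 2.0)$data
  expect_lt(mean(abs(mu_to_hu(rec2) - mu_to_hu(rot_ccw(rec1)))), 1.0)  # HU
})
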