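# Encoder, channel matching, training loops, checkpoints, restorator.

test_that("encoder enforces the unfolded channel layout", {
  cfg <- mini_cfg(nv = 24)
  ph <- make_phantom("random_ellipses", cfg$grid_size, cfg$pixel_spacing, 1)
  unf <- prepare_sample(ph, c(49, 49), 2L, cfg, seed = 1, patch_px = 16L)
  flat <- prepare_sample(ph, c(49, 49), 2L, cfg, seed = 1, patch_px = 16L,
                         unfolded = FALSE)
  enc9 <- tiny_encoder(9L, channels = 6L, layers = 2L, seed = 1)
  enc1 <- tiny_encoder(1L, channels = 6L, layers = 2L, seed = 1)
  expect_equal(enc9$first_kernel, 1L)  # 1x1 kernel over the nine channels
  expect_equal(enc1$first_kernel, 3L)
  expect_error(encode(unf$sq, enc1), "9")
  expect_error(encode(flat$sq, enc9), "channel")
  f <- encode(unf$sq, enc9)
  expect_equal(dim(f), c(dim(unf$sq$data)[1:2], 6L))
  expect_identical(f, encode(unf$sq, enc9))  # bitwise stable across calls
})

test_that("an identity encoder passes the sinogram through unchanged", {
  cfg <- mini_cfg(nv = 24)
  ph <- make_phantom("random_ellipses", cfg$grid_size, cfg$pixel_spacing, 1)
  flat <- prepare_sample(ph, c(49, 49), 2L, cfg, seed = 1, patch_px = 16L,
                         unfolded = FALSE)
  enc <- tiny_encoder(1L, channels = 1L, layers = 2L, seed = 1,
                      input_scale = 1)
  # configure an exact passthrough: center-tap identity first layer, identity
  # second layer, and a zeroed skip contribution is impossible (residual), so
  # use w2 = 0: output = 0 + relu(x) = x for non-negative input
  enc$weights[[1]]$w[] <- 0; enc$weights[[1]]$w[2, 2, 1, 1] <- 1
  enc$weights[[2]]$w[] <- 0
  x <- abs(flat$sq$data)
  flat$sq$data <- x
  expect_equal(encode(flat$sq, enc)[, , 1], x, tolerance = 1e-15)
})

test_that("channel matching is a linear per-position map with exact edge cases", {
  set.seed(2)
  f <- array(rnorm(10 * 8 * 11), c(10, 8, 11))
  # gamma = identity slice (F = 2n+1): zstar equals the features
  expect_equal(channel_match(f, diag(11))$data, f)
  z0 <- channel_match(f, matrix(0, 11, 11))
  expect_true(all(z0$data == 0))
  g1 <- matrix(rnorm(11 * 11), 11); g2 <- matrix(rnorm(11 * 11), 11)
  f2 <- array(rnorm(10 * 8 * 11), c(10, 8, 11))
  expect_equal(channel_match(2 * f - f2, g1)$data,
               2 * channel_match(f, g1)$data - channel_match(f2, g1)$data,
               tolerance = 1e-12)
  expect_equal(channel_match(f, g1 + g2)$data,
               channel_match(f, g1)$data + channel_match(f, g2)$data,
               tolerance = 1e-12)
  expect_error(channel_match(f, matrix(0, 5, 11)), "channels")
  expect_error(channel_match(f, matrix(0, 11, 10)), "odd")
})

test_that("a zero-initialized model reproduces FBP and its first loss exactly", {
  cfg <- mini_cfg(nv = 30)
  ph <- make_phantom("random_ellipses", cfg$grid_size, cfg$pixel_spacing, 3)
  smp <- prepare_sample(ph, c(41, 49), 2L, cfg, seed = 2, patch_px = 16L)
  enc <- tiny_encoder(9L, channels = 8L, layers = 2L, seed = 4)
  mod <- cret_model(enc)
  rec <- cret_reconstruct(mod, smp)
  expect_lt(max(abs(rec$data - mu_to_hu(smp$y_fbp))), 1e-9)
  fit <- train_step1(mod, list(smp), train_config(iters = 1L, seed = 1))
  expect_equal(fit$loss[1], mean(abs(mu_to_hu(smp$y_fbp) - smp$gt_hu)))
})

test_that("training overfits a single patch and follows the lr schedule", {
  cfg <- mini_cfg(nv = 30)
  ph <- make_phantom("random_ellipses", cfg$grid_size, cfg$pixel_spacing, 3)
  smp <- prepare_sample(ph, c(41, 49), 4L, cfg, seed = 2, patch_px = 16L)
  enc <- tiny_encoder(9L, channels = 8L, layers = 2L, seed = 4)
  mod <- cret_model(enc)
  cfgt <- train_config(iters = 200L, lr = 5e-3, seed = 5)
  fit <- train_step1(mod, list(smp), cfgt)
  expect_lt(fit$loss[200], 0.5 * fit$loss[1])  # >= 50% training-loss drop
  # halving schedule at the 0.2/0.4/0.6/0.8 milestones
  expect_equal(unique(fit$lr), 5e-3 * 0.5^(0:4))
  expect_equal(fit$lr[40], 5e-3); expect_equal(fit$lr[41], 2.5e-3)
  # determinism given the seed
  fit2 <- train_step1(mod, list(smp), cfgt)
  expect_identical(fit$model$gamma, fit2$model$gamma)
})

test_that("analytic gradients match central differences", {
  cfg <- mini_cfg(nv = 20)
  ph <- make_phantom("random_ellipses", cfg$grid_size, cfg$pixel_spacing, 6)
  smp <- prepare_sample(ph, c(53, 53), 4L, cfg, seed = 7, patch_px = 8L)
  enc <- tiny_encoder(9L, channels = 4L, layers = 2L, seed = 8)
  mod <- cret_model(enc)
  set.seed(9)
  mod$gamma[] <- rnorm(length(mod$gamma), 0, 0.3)
  mod$beta[] <- rnorm(length(mod$beta), 0, 0.1)
  lg <- cret:::cret_loss_grad(mod, smp)
  eps <- 1e-6
  # all gamma entries
  num <- mod$gamma * 0
  for (i in seq_len(nrow(mod$gamma))) for (j in seq_len(ncol(mod$gamma))) {
    mp <- mod; mp$gamma[i, j] <- mp$gamma[i, j] + eps
    mm <- mod; mm$gamma[i, j] <- mm$gamma[i, j] - eps
    num[i, j] <- (cret:::cret_loss_grad(mp, smp, FALSE)$loss -
                  cret:::cret_loss_grad(mm, smp, FALSE)$loss) / (2 * eps)
  }
  expect_lt(sqrt(sum((num - lg$grads$gamma)^2)) / sqrt(sum(num^2)), 1e-4)
  # a few encoder weights (second layer)
  for (idx in list(c(1, 1, 1, 1), c(2, 3, 2, 4), c(3, 2, 4, 3))) {
    w0 <- mod$encoder$weights[[2]]$w[idx[1], idx[2], idx[3], idx[4]]
    mp <- mod; mp$encoder$weights[[2]]$w[idx[1], idx[2], idx[3], idx[4]] <- w0 + eps
    mm <- mod; mm$encoder$weights[[2]]$w[idx[1], idx[2], idx[3], idx[4]] <- w0 - eps
    nm <- (cret:::cret_loss_grad(mp, smp, FALSE)$loss -
           cret:::cret_loss_grad(mm, smp, FALSE)$loss) / (2 * eps)
    an <- lg$grads$encoder[[2]]$w[idx[1], idx[2], idx[3], idx[4]]
    expect_equal(an, nm, tolerance = 1e-3)
  }
})

test_that("checkpoints round-trip model outputs bitwise", {
  cfg <- mini_cfg(nv = 20)
  ph <- make_phantom("random_ellipses", cfg$grid_size, cfg$pixel_spacing, 6)
  smp <- prepare_sample(ph, c(53, 53), 2L, cfg, seed = 7, patch_px = 8L)
  enc <- tiny_encoder(9L, channels = 4L, layers = 2L, seed = 8)
  mod <- cret_model(enc)
  set.seed(10); mod$gamma[] <- rnorm(length(mod$gamma))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(mod, path)
  back <- load_checkpoint(path)
  expect_identical(cret_reconstruct(back, smp)$data,
                   cret_reconstruct(mod, smp)$data)
  unlink(path)
})

test_that("the restorator is the identity at initialization and plug-and-play", {
  rst <- restorator(channels = 8L, layers = 3L, seed = 1)
  set.seed(3)
  img <- matrix(rnorm(24 * 24, 0, 200), 24, 24)
  expect_equal(restore(rst, img), img, tolerance = 1e-14)
  rec <- recon_image(img, 1, c(0, 0))
  expect_equal(restore(rst, rec)$data, img, tolerance = 1e-14)
})

test_that("restorator training reduces its loss without touching step 1", {
  cfg <- mini_cfg(nv = 30)
  ph <- make_phantom("random_ellipses", cfg$grid_size, cfg$pixel_spacing, 3)
  samples <- list(prepare_sample(ph, c(41, 49), 4L, cfg, seed = 2, patch_px = 16L),
                  prepare_sample(ph, c(57, 57), 4L, cfg, seed = 3, patch_px = 16L))
  enc <- tiny_encoder(9L, channels = 4L, layers = 2L, seed = 4)
  mod <- cret_model(enc)
  before <- cret_reconstruct(mod, samples[[1]])$data
  fit <- train_step2_restorator(mod, samples,
                                train_config(iters = 120L, lr = 2e-3, seed = 6),
                                rst = restorator(channels = 8L, layers = 3L,
                                                 seed = 7))
  expect_lt(mean(tail(fit$loss, 10)), fit$loss[1])
  # step-1 outputs are untouched; disabling the restorator recovers them
  expect_identical(cret_reconstruct(mod, samples[[1]])$data, before)
  expect_error(train_step2_restorator(tempfile(), samples), "missing")
})
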