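#' Tiny convolutional encoder
#'
#' A small CPU-trainable residual CNN over the squeezed sinogram: `layers`
#' convolutions with `channels` feature maps, ReLU between them, and a skip
#' connection from the first activation to the output (no downsampling, shape
#' preserving over views x window). When the input is unfolded (9 channels)
#' the first layer is a 1x1 kernel with nine input channels, otherwise a 3x3
#' kernel with one; later layers are 3x3. The architecture slot accepts
#' externally defined encoders implementing the same `forward`/`backward`
#' contract.
#'
#' @param in_channels 9 for unfolded input, 1 otherwise.
#' @param channels Feature channels F (default 32).
#' @param layers Number of conv layers (>= 2, default 4).
#' @param seed Seed for He-normal initialization.
#' @param input_scale Fixed multiplicative input normalization applied before
#'   the first layer (filtered-sinogram values are of order 1e-2 in 1/mm;
#'   default 50 brings them to order one).
#' @param activation `"relu"` (default) or `"linear"`; with `"linear"` the
#'   encoder collapses to a learned shift-invariant filter bank, a more
#'   constrained model that extrapolates more gracefully to binning scales
#'   outside the training range.
#' @return An `encoder_spec` with a `$weights` list of `(w, b)` pairs.
#' @export
tiny_encoder <- function(in_channels = 9L, channels = 32L, layers = 4L,
                         seed = 0L, input_scale = 50,
                         activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  stopifnot(in_channels %in% c(1L, 9L), layers >= 2, channels >= 1)
  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  k1 <- if (in_channels == 9L) 1L else 3L
  shapes <- vector("list", layers)
  shapes[[1]] <- c(k1, k1, in_channels, channels)
  for (l in seq_len(layers)[-1]) shapes[[l]] <- c(3L, 3L, channels, channels)
  weights <- lapply(shapes, function(s) {
    fan_in <- s[1] * s[2] * s[3]
    list(w = array(stats::rnorm(prod(s), 0, sqrt(2 / fan_in)), s),
         b = numeric(s[4]))
  })
  structure(list(architecture = "tiny_cnn", in_channels = as.integer(in_channels),
                 channels = as.integer(channels), layers = as.integer(layers),
                 first_kernel = k1, input_scale = input_scale,
                 activation = activation,
                 weights = weights), class = "encoder_spec")
}

enc_act <- function(spec, a) {
  if (identical(spec$activation, "linear")) return(a)
  h <- pmax(a, 0); dim(h) <- dim(a); h
}

enc_act_grad <- function(spec, a, g) {
  if (identical(spec$activation, "linear")) return(g)
  g <- g * (a > 0); dim(g) <- dim(a); g
}

# forward pass returning activations for the backward pass
encoder_forward <- function(spec, x) {
  a <- vector("list", spec$layers)  # pre-activations
  h <- vector("list", spec$layers)  # post-activation (last layer: linear)
  a[[1]] <- cpp_conv2d_fw(x, spec$weights[[1]]$w, spec$weights[[1]]$b)
  h[[1]] <- enc_act(spec, a[[1]])
  for (l in seq_len(spec$layers)[-1]) {
    a[[l]] <- cpp_conv2d_fw(h[[l - 1]], spec$weights[[l]]$w, spec$weights[[l]]$b)
    if (l < spec$layers) h[[l]] <- enc_act(spec, a[[l]])
  }
  out <- a[[spec$layers]] + h[[1]]  # residual skip from the first activation
  list(out = out, x = x, a = a, h = h)
}

encoder_backward <- function(spec, cache, gout) {
  L <- spec$layers
  grads <- vector("list", L)
  g <- gout
  gskip <- gout  # gradient reaching h[[1]] through the skip
  for (l in rev(seq_len(L)[-1])) {
    bw <- cpp_conv2d_bw(cache$h[[l - 1]], spec$weights[[l]]$w, g)
    grads[[l]] <- list(w = bw$gw, b = bw$gb)
    g <- bw$gx
    if (l - 1 > 1) g <- enc_act_grad(spec, cache$a[[l - 1]], g)
  }
  # at h[[1]]: chain + skip, then the first activation
  g1 <- enc_act_grad(spec, cache$a[[1]], g + gskip)
  dim(g1) <- dim(cache$a[[1]])
  bw1 <- cpp_conv2d_bw(cache$x, spec$weights[[1]]$w, g1)
  grads[[1]] <- list(w = bw1$gw, b = bw1$gb)
  grads
}

#' Encode a squeezed sinogram
#'
#' Runs the encoder over the squeezed (optionally unfolded) sinogram. The
#' channel layout must match: an unfolded input requires a 1x1/9-channel
#' first layer, a plain input a 3x3/1-channel one.
#'
#' @param sq A `squeezed_sinogram`.
#' @param spec An `encoder_spec` (see [tiny_encoder()]).
#' @return Numeric `N x d x F` feature array; deterministic given the
#'   weights.
#' @export
encode <- function(sq, spec) {
  stopifnot(inherits(sq, "squeezed_sinogram"), inherits(spec, "encoder_spec"))
  nch <- if (sq$unfolded) 9L else 1L
  if (spec$in_channels != nch)
    stop("encoder expects ", spec$in_channels, "-channel input but the ",
         "squeezed sinogram has ", nch,
         " (unfolded input requires a 1x1/9-channel first layer)")
  x <- encoder_input(sq, spec)
  encoder_forward(spec, x)$out
}

encoder_input <- function(sq, spec) {
  x <- sq$data * spec$input_scale
  if (!sq$unfolded) dim(x) <- c(dim(sq$data), 1L)
  x
}

#' Channel-matching 1x1 convolution
#'
#' Per-position linear map from the F encoder channels to the `2n+1` decoder
#' basis coefficients: `z*[i, k, ] = features[i, k, ] %*% gamma + beta`.
#' Linear in the features; with `gamma = 0`, `beta = 0` the downstream CRET
#' reconstruction reduces to plain FBP.
#'
#' @param features Numeric `N x d x F` array.
#' @param gamma Numeric `F x (2n+1)` weight matrix.
#' @param beta Optional length `2n+1` bias (default zeros).
#' @return A [basis_feature_map()].
#' @export
channel_match <- function(features, gamma, beta = NULL) {
  stopifnot(length(dim(features)) == 3)
  dd <- dim(features)
  if (nrow(gamma) != dd[3]) stop("gamma rows must equal the feature channels")
  nb <- ncol(gamma)
  if (nb %% 2 != 1) stop("gamma must map to an odd number (2n+1) of bases")
  if (is.null(beta)) beta <- numeric(nb)
  stopifnot(length(beta) == nb)
  Z <- matrix(features, dd[1] * dd[2], dd[3]) %*% gamma
  Z <- sweep(Z, 2, beta, `+`)
  basis_feature_map(array(Z, c(dd[1], dd[2], nb)),
                    basis_config((nb - 1L) %/% 2L))
}

# decoder-term-only reconstruction (the features-to-image linear map)
cret_delta <- function(sq, roi, zstar) {
  sq0 <- sq
  if (sq$unfolded) sq0$data[, , 5] <- 0 else sq0$data[] <- 0
  cret_backproject(sq0, roi, zstar)
}

#' Assemble a CRET model
#'
#' Bundles the encoder, the channel-matching weights and the basis order.
#' `gamma`/`beta` default to zeros, so a freshly assembled model reproduces
#' plain FBP exactly until trained.
#'
#' @param encoder An `encoder_spec`.
#' @param n Basis order (default 5, decoder dimension `2n+1 = 11`).
#' @param mu_water Water attenuation (1/mm) used for the HU conversion in the
#'   loss and outputs.
#' @param feature_scale Fixed scale between the channel-matching output and
#'   the decoder coefficients actually fed to the back-projection. The
#'   default, `mu_water/1000` (one HU in attenuation units), makes the
#'   trainable weights live at order one, which keeps Adam's per-step updates
#'   commensurate with the loss surface.
#' @return A `cret_model`.
#' @export
cret_model <- function(encoder, n = 5L, mu_water = 0.02,
                       feature_scale = mu_water / 1000) {
  nb <- 2L * as.integer(n) + 1L
  structure(list(encoder = encoder, n = as.integer(n),
                 gamma = matrix(0, encoder$channels, nb), beta = numeric(nb),
                 mu_water = mu_water, feature_scale = feature_scale),
            class = "cret_model")
}

#' Reconstruct an ROI with a CRET model
#'
#' Encoder -> channel matching -> continuous-representation back-projection.
#'
#' @param model A [cret_model()].
#' @param sample A prepared sample (see [prepare_sample()]) or a list with at
#'   least `sq` (squeezed sinogram) and `roi`.
#' @param units `"hu"` (default) or `"mu"`.
#' @return A [recon_image()].
#' @export
cret_reconstruct <- function(model, sample, units = c("hu", "mu")) {
  units <- match.arg(units)
  feats <- encode(sample$sq, model$encoder)
  zstar <- channel_match(feats, model$gamma, model$beta)
  zstar$data <- zstar$data * model$feature_scale
  img <- cret_backproject(sample$sq, sample$roi, zstar)
  if (units == "hu") img$data <- mu_to_hu(img$data, model$mu_water)
  img
}

# loss and gradients of mean L1 (HU scale) for one sample
cret_loss_grad <- function(model, sample, want_grads = TRUE) {
  spec <- model$encoder
  x <- encoder_input(sample$sq, spec)
  fw <- encoder_forward(spec, x)
  dd <- dim(fw$out)
  M <- matrix(fw$out, dd[1] * dd[2], dd[3])
  nb <- 2L * model$n + 1L
  Z <- sweep(M %*% model$gamma, 2, model$beta, `+`)
  zstar <- array(Z * model$feature_scale, c(dd[1], dd[2], nb))
  delta <- cret_delta(sample$sq, sample$roi, zstar)$data
  y_mu <- sample$y_fbp + delta
  y_hu <- mu_to_hu(y_mu, model$mu_water)
  r <- y_hu - sample$gt_hu
  loss <- mean(abs(r))
  if (!is.finite(loss)) stop("non-finite training loss")
  if (!want_grads) return(list(loss = loss, y_hu = y_hu))
  gy_mu <- sign(r) / length(r) * (1000 / model$mu_water)
  GZ <- cret_backproject_grad(gy_mu, sample$sq, sample$roi, nb)
  GZm <- matrix(GZ, dd[1] * dd[2], nb) * model$feature_scale
  ggamma <- crossprod(M, GZm)
  gbeta <- colSums(GZm)
  gfeat <- GZm %*% t(model$gamma)
  dim(gfeat) <- dd
  genc <- encoder_backward(spec, fw, gfeat)
  list(loss = loss, y_hu = y_hu,
       grads = list(gamma = ggamma, beta = gbeta, encoder = genc))
}

# ---- Adam on numeric arrays
adam_step <- function(p, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8, t = 1) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Training configuration
#'
#' @param iters Total iterations (single-sample batches).
#' @param lr Initial Adam learning rate.
#' @param decay_at Fractions of `iters` at which the rate halves (mirrors a
#'   halving schedule at 0.2/0.4/0.6/0.8 of the run).
#' @param decay Multiplicative decay factor at each milestone (default 0.5).
#' @param seed Seed controlling sample order.
#' @param scales Binning scales the training samples may come from.
#' @param augment Optional data-augmentation hook, `function(sample)`;
#'   default `NULL` (no-op).
#' @return A `train_config` list.
#' @export
train_config <- function(iters = 300L, lr = 1e-3,
                         decay_at = c(0.2, 0.4, 0.6, 0.8), decay = 0.5,
                         seed = 0L, scales = c(1L, 2L, 4L), augment = NULL) {
  stopifnot(lr > 0, iters >= 1)
  structure(list(iters = as.integer(iters), lr = lr, decay_at = decay_at,
                 decay = decay, seed = as.integer(seed),
                 scales = as.integer(scales), augment = augment),
            class = "train_config")
}

#' Step-1 training: encoder + channel matching
#'
#' Minimizes the mean L1 discrepancy (HU) between the CRET ROI reconstruction
#' and the ground-truth patch over prepared samples, with Adam and a halving
#' learning-rate schedule. Samples are visited in a seeded random order, one
#' per iteration. The loss at iteration 1 of a freshly assembled model equals
#' the FBP L1 error exactly (gamma and beta start at zero).
#'
#' @param model A [cret_model()].
#' @param samples List of prepared samples (see [prepare_sample()]).
#' @param cfg A [train_config()].
#' @return List with the trained `model`, per-iteration `loss` vector, and
#'   the learning-rate trace `lr`.
#' @export
train_step1 <- function(model, samples, cfg = train_config()) {
  stopifnot(inherits(model, "cret_model"), length(samples) >= 1)
  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)
  order_idx <- sample(rep(seq_along(samples),
                          length.out = cfg$iters + length(samples)))
  st_gamma <- list(m = model$gamma * 0, v = model$gamma * 0)
  st_beta <- list(m = model$beta * 0, v = model$beta * 0)
  st_enc <- lapply(model$encoder$weights, function(l)
    list(w = list(m = l$w * 0, v = l$w * 0),
         b = list(m = l$b * 0, v = l$b * 0)))
  milestones <- ceiling(cfg$decay_at * cfg$iters)
  losses <- numeric(cfg$iters)
  lrs <- numeric(cfg$iters)
  lr <- cfg$lr
  for (it in seq_len(cfg$iters)) {
    lr <- cfg$lr * cfg$decay^sum(it > milestones)
    lrs[it] <- lr
    smp <- samples[[order_idx[it]]]
    if (!is.null(cfg$augment)) smp <- cfg$augment(smp)
    lg <- cret_loss_grad(model, smp)
    losses[it] <- lg$loss
    up <- adam_step(model$gamma, lg$grads$gamma, st_gamma, lr, t = it)
    model$gamma <- up$p; st_gamma <- up$st
    up <- adam_step(model$beta, lg$grads$beta, st_beta, lr, t = it)
    model$beta <- up$p; st_beta <- up$st
    for (l in seq_along(model$encoder$weights)) {
      up <- adam_step(model$encoder$weights[[l]]$w, lg$grads$encoder[[l]]$w,
                      st_enc[[l]]$w, lr, t = it)
      model$encoder$weights[[l]]$w <- up$p; st_enc[[l]]$w <- up$st
      up <- adam_step(model$encoder$weights[[l]]$b, lg$grads$encoder[[l]]$b,
                      st_enc[[l]]$b, lr, t = it)
      model$encoder$weights[[l]]$b <- up$p; st_enc[[l]]$b <- up$st
    }
  }
  list(model = model, loss = losses, lr = lrs)
}

#' Save / load model checkpoints
#'
#' Round-tripping a checkpoint reproduces model outputs bitwise (plain RDS of
#' the weight arrays).
#'
#' @param model A `cret_model` or `restorator`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint` the
#'   restored object.
#' @export
save_checkpoint <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
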