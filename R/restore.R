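#' Image-domain restorator
#'
#' A small residual CNN applied (optionally) after reconstruction to remove
#' residual blurring and artifacts: `restore(x) = x + 500 * net(x / 500)` on
#' HU images, where `net` is a stack of 3x3 convolutions with ReLU. The last
#' layer is zero-initialized, so a freshly created restorator is exactly the
#' identity; it is trained separately from (and never modifies) the Step-1
#' model, and can be swapped for any externally defined image-to-image model
#' implementing the same contract.
#'
#' @param channels Hidden feature channels (default 16).
#' @param layers Number of conv layers (default 6).
#' @param seed Seed for the He-normal initialization of the hidden layers.
#' @return A `restorator`.
#' @export
restorator <- function(channels = 16L, layers = 6L, seed = 0L) {
  stopifnot(layers >= 2, channels >= 1)
  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  shapes <- vector("list", layers)
  shapes[[1]] <- c(3L, 3L, 1L, channels)
  for (l in seq_len(layers)[-c(1, layers)]) shapes[[l]] <- c(3L, 3L, channels, channels)
  shapes[[layers]] <- c(3L, 3L, channels, 1L)
  weights <- lapply(seq_along(shapes), function(l) {
    s <- shapes[[l]]
    if (l == length(shapes)) return(list(w = array(0, s), b = numeric(s[4])))
    fan_in <- s[1] * s[2] * s[3]
    list(w = array(stats::rnorm(prod(s), 0, sqrt(2 / fan_in)), s),
         b = numeric(s[4]))
  })
  structure(list(channels = as.integer(channels), layers = as.integer(layers),
                 scale = 500, weights = weights), class = "restorator")
}

restorator_forward <- function(rst, x_hu) {
  u <- x_hu / rst$scale
  dim(u) <- c(dim(x_hu), 1L)
  a <- vector("list", rst$layers); h <- vector("list", rst$layers)
  cur <- u
  for (l in seq_len(rst$layers)) {
    a[[l]] <- cpp_conv2d_fw(cur, rst$weights[[l]]$w, rst$weights[[l]]$b)
    if (l < rst$layers) { h[[l]] <- pmax(a[[l]], 0); dim(h[[l]]) <- dim(a[[l]]); cur <- h[[l]] }
  }
  out <- x_hu + rst$scale * matrix(a[[rst$layers]], nrow(x_hu), ncol(x_hu))
  list(out = out, u = u, a = a, h = h)
}

restorator_backward <- function(rst, cache, gout_hu) {
  L <- rst$layers
  grads <- vector("list", L)
  g <- gout_hu * rst$scale
  dim(g) <- c(dim(gout_hu), 1L)
  for (l in rev(seq_len(L))) {
    inp <- if (l == 1) cache$u else cache$h[[l - 1]]
    bw <- cpp_conv2d_bw(inp, rst$weights[[l]]$w, g)
    grads[[l]] <- list(w = bw$gw, b = bw$gb)
    if (l > 1) { g <- bw$gx * (cache$a[[l - 1]] > 0); dim(g) <- dim(cache$a[[l - 1]]) }
  }
  grads
}

#' Apply the restorator
#' @param rst A [restorator()].
#' @param image A [recon_image()] (HU) or bare HU matrix.
#' @return Same type as the input, restored.
#' @export
restore <- function(rst, image) {
  stopifnot(inherits(rst, "restorator"))
  if (inherits(image, "recon_image")) {
    image$data <- restorator_forward(rst, image$data)$out
    image
  } else restorator_forward(rst, image)$out
}

#' Step-2 training: image-domain restorator
#'
#' Transfer-learning stage: the Step-1 model is frozen, its ROI
#' reconstructions (HU) are paired with the ground-truth patches, and the
#' restorator is trained with L1/Adam on those pairs. The Step-1 model is
#' required and never updated (plug-and-play: disabling the restorator leaves
#' Step-1 outputs untouched).
#'
#' @param step1_model A trained, frozen [cret_model()] (or a checkpoint path).
#' @param samples Prepared samples (see [prepare_sample()]).
#' @param cfg A [train_config()] (`scales` unused here).
#' @param rst Optional starting [restorator()].
#' @return List with trained `restorator` and per-iteration `loss`.
#' @export
train_step2_restorator <- function(step1_model, samples, cfg = train_config(),
                                   rst = restorator()) {
  if (is.character(step1_model)) {
    if (!file.exists(step1_model)) stop("missing step-1 checkpoint: ", step1_model)
    step1_model <- load_checkpoint(step1_model)
  }
  stopifnot(inherits(step1_model, "cret_model"), inherits(rst, "restorator"))
  inputs <- lapply(samples, function(s) cret_reconstruct(step1_model, s)$data)
  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)
  order_idx <- sample(rep(seq_along(samples),
                          length.out = cfg$iters + length(samples)))
  st <- lapply(rst$weights, function(l)
    list(w = list(m = l$w * 0, v = l$w * 0),
         b = list(m = l$b * 0, v = l$b * 0)))
  milestones <- ceiling(cfg$decay_at * cfg$iters)
  losses <- numeric(cfg$iters)
  for (it in seq_len(cfg$iters)) {
    lr <- cfg$lr * cfg$decay^sum(it > milestones)
    j <- order_idx[it]
    fw <- restorator_forward(rst, inputs[[j]])
    r <- fw$out - samples[[j]]$gt_hu
    losses[it] <- mean(abs(r))
    if (!is.finite(losses[it])) stop("non-finite restorator loss")
    g <- sign(r) / length(r)
    grads <- restorator_backward(rst, fw, g)
    for (l in seq_along(rst$weights)) {
      up <- adam_step(rst$weights[[l]]$w, grads[[l]]$w, st[[l]]$w, lr, t = it)
      rst$weights[[l]]$w <- up$p; st[[l]]$w <- up$st
      up <- adam_step(rst$weights[[l]]$b, grads[[l]]$b, st[[l]]$b, lr, t = it)
      rst$weights[[l]]$b <- up$p; st[[l]]$b <- up$st
    }
  }
  list(restorator = rst, loss = losses)
}
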