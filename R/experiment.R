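#' Desk-scale study configuration
#'
#' The fixed simulation conditions used by the package's own experiments and
#' tests: a flat-detector fan-beam scanner (SID 600 mm, SDD 1000 mm, 240
#' views over a full turn), random-ellipse phantoms of 128 x 128 pixels at
#' 0.3 mm spacing, Poisson noise at 1e6 incident photons, 32 x 32-pixel
#' ground-truth patches, training binning scales \{1, 2, 4\}, and the
#' squeezing protocol `d = 64/s`, `pad = 256/s`.
#'
#' Two detector layouts are used. The default (512 cells of 2 mm) is coarse
#' relative to the image grid (iso-scaled pitch 1.2 mm vs 0.3 mm pixels);
#' its purpose is the squeeze-window protocol guarantee, where `d = 64`
#' must cover a 128 x 128-pixel patch at `s = 1`. The learning study
#' instead uses 1024 cells of 1 mm (iso-scaled pitch 0.6 mm, twice the
#' ground-truth pixel): a scanner whose native sampling is comparable to
#' the reconstruction grid, the regime where detector binning — not the
#' baseline geometry — is the resolution bottleneck that the learned
#' correction is asked to undo.
#'
#' @param n_views Number of views (default 240).
#' @param grid_size Phantom side length in pixels (default 128).
#' @param n_detectors,det_pitch Detector layout (defaults 512 x 2 mm).
#' @return A named list of study parameters.
#' @export
desk_study_config <- function(n_views = 240L, grid_size = 128L,
                              n_detectors = 512L, det_pitch = 2.0) {
  list(
    source_to_iso = 600, source_to_det = 1000,
    n_detectors = as.integer(n_detectors), det_pitch = det_pitch,
    n_views = as.integer(n_views),
    grid_size = as.integer(grid_size), pixel_spacing = 0.3,
    patch_px = 32L, photons_i0 = 1e6, mu_water = 0.02,
    train_scales = c(1L, 2L, 4L), d_base = 64L, pad_base = 256L,
    data_range = 400
  )
}

#' @rdname desk_study_config
#' @export
learning_study_config <- function(n_views = 240L, grid_size = 128L) {
  desk_study_config(n_views, grid_size, n_detectors = 1024L, det_pitch = 1.0)
}

#' Scanner geometry of a study configuration
#' @param cfg A [desk_study_config()] list.
#' @return A [fanbeam_geometry()].
#' @export
study_geometry <- function(cfg = desk_study_config()) {
  fanbeam_geometry(cfg$source_to_iso, cfg$source_to_det, cfg$n_detectors,
                   cfg$det_pitch, n_views = cfg$n_views)
}

#' Pixel-aligned ROI inside a phantom
#'
#' An [roi_spec()] whose output pixel centers coincide with phantom pixel
#' centers, so the ground-truth patch is an exact crop: the patch is the
#' `size_px x size_px` block whose top-left pixel is `corner` (row, col,
#' 1-based).
#'
#' @param phantom A `phantom`.
#' @param corner Integer (row, col) of the top-left patch pixel.
#' @param size_px Patch side length in pixels.
#' @param s Binning scale recorded in the spec.
#' @return List with `roi` ([roi_spec()]) and `gt_hu` (the cropped HU patch).
#' @export
pixel_aligned_roi <- function(phantom, corner, size_px, s = 1L) {
  stopifnot(all(corner >= 1), all(corner + size_px - 1 <= phantom$grid_size))
  g <- phantom_grid(phantom)
  cols <- corner[2]:(corner[2] + size_px - 1)
  rows <- corner[1]:(corner[1] + size_px - 1)
  center <- c(mean(g$x[cols]), mean(g$y[rows]))
  list(roi = roi_spec(center, size_px * phantom$pixel_spacing, size_px, s = s),
       gt_hu = phantom$values[rows, cols])
}

#' Prepare a training/evaluation sample
#'
#' Runs the full simulation front end for one (phantom, ROI, binning scale)
#' triple: forward projection, Poisson noise, detector binning, cosine
#' weighting, ramp filtering, unfolding (optional), ROI-center indexing and
#' squeezing; precomputes the plain-FBP ROI reconstruction (the constant part
#' of the CRET output) and the ground-truth patch.
#'
#' @param phantom A `phantom`.
#' @param corner Top-left (row, col) of the pixel-aligned patch.
#' @param s Binning scale.
#' @param cfg A [desk_study_config()].
#' @param seed Noise seed.
#' @param unfolded Apply sinogram unfolding before squeezing (default TRUE).
#' @param d,pad Window and padding; default the protocol values
#'   `d_base/s`, `pad_base/s`.
#' @param noise Apply Poisson noise (default TRUE).
#' @param patch_px Patch side length in pixels (default `cfg$patch_px`).
#' @return A `cret_sample` list: `sq`, `roi`, `gt_hu`, `y_fbp` (1/mm), `s`,
#'   `seed`.
#' @export
prepare_sample <- function(phantom, corner, s, cfg = desk_study_config(),
                           seed = 0L, unfolded = TRUE, d = NULL, pad = NULL,
                           noise = TRUE, patch_px = cfg$patch_px) {
  geom <- study_geometry(cfg)
  ar <- pixel_aligned_roi(phantom, corner, patch_px, s = s)
  sino <- forward_project(phantom, geom, mu_water = cfg$mu_water)
  if (noise) sino <- add_poisson_noise(sino, cfg$photons_i0, seed = seed)
  sino <- bin_detector(sino, s)
  z <- ramp_filter(cosine_weight(sino))
  if (unfolded) z <- unfold(z)
  if (is.null(d)) d <- max(cfg$d_base %/% s, 8L)
  if (is.null(pad)) pad <- max(cfg$pad_base %/% s, d %/% 2L)
  ci <- roi_center_index(ar$roi, z$geometry)
  sq <- squeeze_sinogram(z, ci, d = d, pad = pad)
  y_fbp <- cret_backproject(sq, ar$roi, features = NULL)
  structure(list(sq = sq, roi = ar$roi, gt_hu = ar$gt_hu,
                 y_fbp = y_fbp$data, s = as.integer(s), seed = seed),
            class = "cret_sample")
}

# interior patch corners (patch fully inside the body ellipse), seeded
draw_patch_corners <- function(phantom, size_px, k, seed) {
  if (exists(".Random.seed", envir = globalenv()))
    old_seed <- get(".Random.seed", envir = globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  mask <- interior_mask(phantom, shrink = 0.85)
  gs <- phantom$grid_size
  ok <- function(r, c) {
    rr <- c(r, r + size_px - 1); cc <- c(c, c + size_px - 1)
    all(mask[rr[1], cc], mask[rr[2], cc], mask[rr, cc[1]], mask[rr, cc[2]])
  }
  out <- list()
  guard <- 0
  while (length(out) < k && guard < 2000) {
    r <- sample.int(gs - size_px + 1, 1); c <- sample.int(gs - size_px + 1, 1)
    if (ok(r, c)) out[[length(out) + 1]] <- c(r, c)
    guard <- guard + 1
  }
  if (length(out) < k) {
    ctr <- as.integer((gs - size_px) / 2) + 1L
    while (length(out) < k) out[[length(out) + 1]] <- c(ctr, ctr)
  }
  out
}

#' Build a desk-scale dataset
#'
#' Random-ellipse phantoms with interior, pixel-aligned patches at seeded
#' binning scales; the workhorse behind the training and evaluation runs.
#'
#' @param n_phantoms Number of phantoms.
#' @param rois_per_phantom Patches per phantom.
#' @param scales Binning scales to cycle through.
#' @param cfg A [desk_study_config()].
#' @param seed Base seed (phantom `i` uses `seed + i`).
#' @param unfolded,d,pad Passed to [prepare_sample()].
#' @return List of `cret_sample`s.
#' @export
make_dataset <- function(n_phantoms, rois_per_phantom = 1L,
                         scales = c(1L, 2L, 4L), cfg = desk_study_config(),
                         seed = 0L, unfolded = TRUE, d = NULL, pad = NULL) {
  samples <- list()
  si <- 0L
  for (i in seq_len(n_phantoms)) {
    ph <- make_phantom("random_ellipses", cfg$grid_size, cfg$pixel_spacing,
                       seed = seed + i)
    corners <- draw_patch_corners(ph, cfg$patch_px, rois_per_phantom,
                                  seed = seed + 1000L + i)
    for (j in seq_len(rois_per_phantom)) {
      s <- scales[(si %% length(scales)) + 1L]
      si <- si + 1L
      samples[[length(samples) + 1]] <-
        prepare_sample(ph, corners[[j]], s, cfg,
                       seed = seed + 2000L + si, unfolded = unfolded,
                       d = d, pad = pad)
    }
  }
  samples
}

#' Run a reconstruction comparison experiment
#'
#' Reconstructs every sample with plain FBP, the CRET model and (optionally)
#' CRET + restorator, and evaluates PSNR/SSIM against the ground-truth patch.
#' A failing method is recorded as `NA` for its metrics without stopping the
#' other methods.
#'
#' @param samples Prepared samples (see [make_dataset()]).
#' @param model A trained [cret_model()], or `NULL` to skip CRET.
#' @param rst A trained [restorator()], or `NULL` to skip CRET+.
#' @param cfg A [desk_study_config()] (supplies the PSNR/SSIM `data_range`).
#' @return A data.frame with one row per (method, sample): method, s,
#'   sample, psnr, ssim, seed.
#' @export
run_experiment <- function(samples, model = NULL, rst = NULL,
                           cfg = desk_study_config()) {
  rows <- list()
  for (k in seq_along(samples)) {
    smp <- samples[[k]]
    outs <- list(fbp = mu_to_hu(smp$y_fbp, cfg$mu_water))
    if (!is.null(model)) {
      outs$cret <- tryCatch(cret_reconstruct(model, smp)$data,
                            error = function(e) NULL)
      if (!is.null(rst) && !is.null(outs$cret))
        outs$cret_plus <- tryCatch(restore(rst, outs$cret),
                                   error = function(e) NULL)
    }
    for (m in names(outs)) {
      ok <- !is.null(outs[[m]])
      rows[[length(rows) + 1]] <- data.frame(
        method = m, s = smp$s, sample = k,
        psnr = if (ok) psnr(outs[[m]], smp$gt_hu, cfg$data_range) else NA_real_,
        ssim = if (ok) ssim(outs[[m]], smp$gt_hu, cfg$data_range) else NA_real_,
        seed = smp$seed)
    }
  }
  do.call(rbind, rows)
}
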