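#' @title Synthetic phantoms in Hounsfield units
#' @description Ellipse-based phantoms on a square pixel grid. Values are in
#'   Hounsfield units with the air background at -1000 HU; the generating
#'   ellipse parameters are recorded so analytic oracles (chord lengths, point
#'   projections) can be evaluated against the same description.
#' @name phantoms
NULL

# Modified (contrast-enhanced) Shepp-Logan ellipse table in the unit disk:
# columns: additive value v, semi-axis a, semi-axis b, x0, y0, angle (deg).
shepp_logan_table <- function() {
  matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.10, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.10, 0.0230, 0.0460,  0.06, -0.6050,   0),
    ncol = 6, byrow = TRUE,
    dimnames = list(NULL, c("value", "a", "b", "x0", "y0", "angle_deg")))
}

# Evaluate a sum of ellipses (HU deltas over a -1000 HU background) at world
# coordinates. `ellipses` is a data.frame with hu, a, b, x0, y0, angle (rad).
eval_ellipses_hu <- function(ellipses, x, y) {
  v <- rep(-1000, length(x))
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    ca <- cos(e$angle); sa <- sin(e$angle)
    X <- x - e$x0; Y <- y - e$y0
    inside <- ((X * ca + Y * sa) / e$a)^2 + ((-X * sa + Y * ca) / e$b)^2 <= 1
    v[inside] <- v[inside] + e$hu
  }
  v
}

pixel_centers <- function(grid_size, pixel_spacing) {
  half <- (grid_size - 1) / 2
  (seq_len(grid_size) - 1 - half) * pixel_spacing
}

new_phantom <- function(values, grid_size, pixel_spacing, ellipses,
                        kind, seed = NA_integer_, lesions = list()) {
  structure(list(values = values, grid_size = as.integer(grid_size),
                 pixel_spacing = pixel_spacing, ellipses = ellipses,
                 kind = kind, seed = seed, lesions = lesions),
            class = "phantom")
}

#' Make a synthetic phantom
#'
#' `shepp_logan` evaluates the modified Shepp-Logan ellipse table (unit-disk
#' coordinates scaled to the grid half-extent), mapped to HU as
#' `HU = 1000*v - 1000` so air is -1000 HU and the skull 0 HU.
#' `random_ellipses` draws a water-equivalent body ellipse plus 3-8 random
#' interior ellipses with contrasts in +/-150 HU.
#'
#' @param kind `"shepp_logan"` or `"random_ellipses"`.
#' @param grid_size Pixels per side (>= 16); the grid is square.
#' @param pixel_spacing Pixel size in mm.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `phantom`: HU matrix (`grid_size^2`, row-major image convention,
#'   row 1 at the top / +y), spacing, and the generating ellipse list.
#' @export
make_phantom <- function(kind = c("shepp_logan", "random_ellipses"),
                         grid_size, pixel_spacing = 1, seed = 0L) {
  if (!is.character(kind) || !kind[1] %in% c("shepp_logan", "random_ellipses"))
    stop("unknown phantom kind: ", kind[1])
  kind <- kind[1]
  stopifnot(grid_size >= 16, pixel_spacing > 0)
  half <- grid_size * pixel_spacing / 2

  if (kind == "shepp_logan") {
    tab <- shepp_logan_table()
    ell <- data.frame(hu = 1000 * tab[, "value"],
                      a = tab[, "a"] * half, b = tab[, "b"] * half,
                      x0 = tab[, "x0"] * half, y0 = tab[, "y0"] * half,
                      angle = tab[, "angle_deg"] * pi / 180)
  } else {
    if (exists(".Random.seed", envir = globalenv()))
      old_seed <- get(".Random.seed", envir = globalenv())
    else old_seed <- NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    rng <- local({ set.seed(seed); n <- sample(3:8, 1)
      body_a <- runif(1, 0.70, 0.85) * half
      body_b <- runif(1, 0.70, 0.85) * half
      inner <- data.frame(
        hu = runif(n, -150, 150),
        a = runif(n, 0.05, 0.30) * half,
        b = runif(n, 0.05, 0.30) * half,
        x0 = runif(n, -0.45, 0.45) * half,
        y0 = runif(n, -0.45, 0.45) * half,
        angle = runif(n, 0, pi))
      rbind(data.frame(hu = 1000, a = body_a, b = body_b, x0 = 0, y0 = 0,
                       angle = 0), inner)
    })
    ell <- rng
  }

  xs <- pixel_centers(grid_size, pixel_spacing)
  grid <- expand.grid(y = rev(xs), x = xs)  # row 1 = top (+y)
  vals <- eval_ellipses_hu(ell, grid$x, grid$y)
  values <- matrix(vals, grid_size, grid_size)
  new_phantom(values, grid_size, pixel_spacing, ell, kind, seed)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom:%s> %dx%d @ %.3g mm, HU range [%.0f, %.0f]\n",
              x$kind, x$grid_size, x$grid_size, x$pixel_spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

#' World coordinates of a phantom pixel grid
#' @param phantom A `phantom`.
#' @return List with vectors `x` (by column) and `y` (by row, descending).
#' @export
phantom_grid <- function(phantom) {
  xs <- pixel_centers(phantom$grid_size, phantom$pixel_spacing)
  list(x = xs, y = rev(xs))
}

#' Insert a Gaussian lesion
#'
#' Adds an isotropic Gaussian bump of the given peak amplitude (HU) and
#' standard deviation sigma (in pixels of the phantom grid). The bump is
#' truncated at a radius of 6 sigma, so pixels further away are untouched;
#' insertion is additive, hence order-independent for disjoint lesions.
#'
#' @param phantom A `phantom`.
#' @param center World (x, y) mm of the lesion center; must lie on the grid.
#' @param sigma Standard deviation in pixel units (> 0). Default 0.75.
#' @param peak Peak amplitude in HU. Default 100.
#' @return The phantom with the lesion added and recorded in `$lesions`.
#' @export
insert_lesion <- function(phantom, center, sigma = 0.75, peak = 100) {
  stopifnot(sigma > 0, is.finite(peak), length(center) == 2)
  g <- phantom_grid(phantom)
  half <- phantom$grid_size * phantom$pixel_spacing / 2
  if (any(abs(center) > half)) stop("lesion center outside the phantom grid")
  # pixel coordinates (possibly fractional) of the center
  cc <- center[1] / phantom$pixel_spacing + (phantom$grid_size - 1) / 2
  cr <- (phantom$grid_size - 1) / 2 - center[2] / phantom$pixel_spacing
  rows <- seq_len(phantom$grid_size) - 1
  dr2 <- outer((rows - cr)^2, (rows - cc)^2, "+")  # row x col squared distance
  bump <- peak * exp(-dr2 / (2 * sigma^2))
  bump[dr2 > (6 * sigma)^2] <- 0
  phantom$values <- phantom$values + bump
  phantom$lesions <- c(phantom$lesions,
                       list(list(center = center, sigma = sigma, peak = peak)))
  phantom
}

#' Hounsfield units to linear attenuation
#'
#' `mu = mu_water * (HU/1000 + 1)`, clipped below at 0 (air and anything
#' below -1000 HU attenuate nothing).
#'
#' @param values_hu Numeric array of HU values.
#' @param mu_water Attenuation of water in 1/mm (> 0). Default 0.02.
#' @return Array of attenuation coefficients (1/mm), same shape.
#' @export
hu_to_mu <- function(values_hu, mu_water = 0.02) {
  stopifnot(mu_water > 0)
  pmax(mu_water * (values_hu / 1000 + 1), 0)
}

#' Linear attenuation to Hounsfield units
#' @param mu Attenuation array (1/mm).
#' @param mu_water Attenuation of water in 1/mm. Default 0.02.
#' @return HU array, `1000 * (mu/mu_water - 1)`.
#' @export
mu_to_hu <- function(mu, mu_water = 0.02) 1000 * (mu / mu_water - 1)

#' Interior mask of an ellipse phantom
#'
#' Logical mask of pixels strictly inside the outermost (body) ellipse, the
#' ellipse shrunk by `shrink` to exclude the edge transition band; used to
#' restrict reconstruction error measurements to the object interior.
#'
#' @param phantom A `phantom`.
#' @param shrink Fraction of the body semi-axes retained (default 0.9).
#' @return Logical matrix of the phantom's shape.
#' @export
interior_mask <- function(phantom, shrink = 0.9) {
  e <- phantom$ellipses[1, ]
  g <- phantom_grid(phantom)
  X <- outer(rep(1, length(g$y)), g$x) - e$x0
  Y <- outer(g$y, rep(1, length(g$x))) - e$y0
  ca <- cos(e$angle); sa <- sin(e$angle)
  ((X * ca + Y * sa) / (shrink * e$a))^2 +
    ((-X * sa + Y * ca) / (shrink * e$b))^2 <= 1
}
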