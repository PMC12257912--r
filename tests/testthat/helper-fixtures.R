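# Small fixtures shared across the suite. Everything is generated in code;
# geometries are kept small so individual tests run in well under a second.

# modest scanner: 600/1000 mm, coarse detector, reduced view count
tiny_geom <- function(nv = 90L, ndet = 128L, pitch = 3.2) {
  fanbeam_geometry(600, 1000, ndet, pitch, n_views = nv)
}

# uniform disk phantom: water-equivalent (0 HU) disk of radius r_mm on air
disk_phantom <- function(grid_size = 64L, pixel_spacing = 2.0, r_mm = 40) {
  ph <- make_phantom("shepp_logan", grid_size, pixel_spacing, 0L)
  ph$values[] <- -1000
  g <- phantom_grid(ph)
  ph$values[outer(g$y^2, g$x^2, "+") <= r_mm^2] <- 0
  ph$ellipses <- data.frame(hu = 1000, a = r_mm, b = r_mm, x0 = 0, y0 = 0,
                            angle = 0)
  ph$kind <- "disk"
  ph
}

# a filtered sinogram with arbitrary (seeded) values, for tests that exercise
# squeezing / decoding independently of the physics front end
random_filtered_sinogram <- function(geom, seed = 1L, sd = 0.01) {
  set.seed(seed)
  z <- matrix(rnorm(n_views(geom) * geom$n_detectors, 0, sd),
              n_views(geom), geom$n_detectors)
  sinogram(z, geom, stage = "filtered")
}

# small study configuration for learning tests (fewer views than the desk
# study so each iteration stays cheap)
mini_cfg <- function(nv = 60L) desk_study_config(n_views = nv)

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
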