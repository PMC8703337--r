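# Shared fixtures, built in code. Heavier scenes are cached per test run.

.scene_cache <- new.env(parent = emptyenv())

# default desk-scale scene (10 seeds, no overlap), cached
cached_scene <- function(rng_seed = 42L, ...) {
  key <- paste0("scene_", rng_seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- generate_scene(scene_spec(rng_seed = rng_seed, ...))
  .scene_cache[[key]]
}

# small constant hypercube for I/O and algebra tests
const_cube <- function(value, ny = 4L, nx = 5L, L = 3L,
                       wavelengths = seq(600, 700, length.out = L),
                       dtype_code = 4L) {
  hypercube(array(value, c(ny, nx, L)), wavelengths = wavelengths,
            dtype_code = dtype_code)
}

# deterministic integer-valued random cube
random_cube <- function(seed, ny = 4L, nx = 5L, L = 3L, dtype_code = 12L,
                        interleave = "bil") {
  set.seed(seed)
  hypercube(array(sample.int(4000L, ny * nx * L, replace = TRUE),
                  c(ny, nx, L)),
            wavelengths = seq(600, 700, length.out = L),
            interleave = interleave, dtype_code = dtype_code)
}

# render a plain intensity scene (3 bands) from a list of ellipses:
# background 100, seeds 1000 counts
ellipse_scene_cube <- function(ellipses, nx = 160L, ny = 160L, L = 3L) {
  labels <- matrix(0L, ny, nx)
  for (i in seq_along(ellipses)) {
    e <- ellipses[[i]]
    m <- seedhsi:::.raster_ellipse(nx, ny, e$cx, e$cy, e$a, e$b, e$theta)
    labels[m] <- i
  }
  slice <- matrix(100, ny, nx)
  slice[labels > 0L] <- 1000
  hypercube(array(rep(slice, L), c(ny, nx, L)),
            wavelengths = seq(600, 700, length.out = L))
}

ellipse <- function(cx, cy, a, b, theta = 0) {
  list(cx = cx, cy = cy, a = a, b = b, theta = theta)
}

# Closed-form standard error of a group mean reflectance curve: independent
# pixel noise averaged over n pixels, plus the white/dark reference noise
# shared by all pixels in a column (column_weights = pixels per column /
# total, so the shared term averages with the exact column weighting).
group_mean_se <- function(noise_sd, white, dark, n_pixels, column_weights,
                          refl, n_ref_lines) {
  delta <- white - dark
  sd_r <- noise_sd / delta
  w2 <- sum((column_weights / sum(column_weights))^2)
  ref_var <- sd_r^2 * ((1 - refl)^2 + refl^2) * w2 / n_ref_lines
  sqrt(sd_r^2 / n_pixels + ref_var)
}

# Band-wise z-scores of a recovered curve; "recovered within noise" means no
# more than the multiplicity-expected number of 3-sigma exceedances among the
# simultaneous per-band checks, and no band beyond 5 sigma (which would
# indicate a systematic bias rather than noise).
expect_curve_within_noise <- function(got, planted, se, info = "") {
  z <- abs(got - planted) / se
  testthat::expect_lte(sum(z > 3), 2L, label = paste(info, "bands beyond 3 SE"))
  testthat::expect_lt(max(z), 5, label = paste(info, "max |z|"))
}
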