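# Per-seed cube extraction, mean spectra and CSV/ENVI output plumbing.

mask_from_labels <- function(labels) {
  seedhsi:::.seed_mask_from_labels(labels)
}

test_that("one cropped cube per seed, bounding boxes and conservation", {
  cube <- random_cube(5, ny = 30L, nx = 20L, L = 4L)
  labels <- matrix(0L, 30, 20)
  labels[10:20, 5:9] <- 1L
  labels[25:28, 12:18] <- 2L
  masks <- mask_from_labels(labels)
  cubes <- extract_seed_cubes(cube, masks)
  expect_length(cubes, 2L)
  expect_identical(dim(cubes[[1]]), c(11L, 5L, 4L))
  expect_identical(dim(cubes[[2]]), c(4L, 7L, 4L))
  total_out <- sum(vapply(cubes, function(cc) sum(cc$data), numeric(1)))
  total_in <- sum(cube$data * as.numeric(rep(labels > 0L, 4L)))
  expect_equal(total_out, total_in)
  expect_error(extract_seed_cubes(random_cube(5, ny = 10L, nx = 10L), masks),
               "shape")
})

test_that("mean spectra average per seed in label order", {
  cube <- const_cube(0, ny = 10L, nx = 10L, L = 3L)
  labels <- matrix(0L, 10, 10)
  labels[2:4, 2:4] <- 1L
  labels[7:8, 7] <- 2L
  cube$data[2:4, 2:4, ] <- rep(c(0.2, 0.5, 0.9), each = 9)
  cube$data[7, 7, ] <- 0
  cube$data[8, 7, ] <- 1
  masks <- mask_from_labels(labels)
  sp <- mean_spectra(cube, masks, image_id = "img1")
  expect_identical(nrow(sp$meta), 2L)
  expect_equal(sp$spectra[1, ], c(0.2, 0.5, 0.9))
  expect_equal(sp$spectra[2, ], c(0.5, 0.5, 0.5))
  expect_identical(sp$meta$pixel_count, c(9L, 2L))
})

test_that("mean spectra commute with band trimming", {
  sc <- cached_scene(rng_seed = 42L)
  m <- segment_scene(sc$raw, segmentation_params(min_pixels = 80L))
  cal <- calibrate(sc$raw, sc$refs)
  a <- mean_spectra(trim_bands(cal, 700, 1500)$cube, m)
  b <- trim_bands(calibrate(sc$raw, sc$refs), 700, 1500)
  keep <- b$window$retained_indices
  full <- mean_spectra(cal, m)
  expect_equal(a$spectra, full$spectra[, keep, drop = FALSE])
})

test_that("CSV output round-trips and respects the overwrite flag", {
  sc <- cached_scene(rng_seed = 42L)
  m <- segment_scene(sc$raw, segmentation_params(min_pixels = 80L))
  cal <- trim_bands(calibrate(sc$raw, sc$refs))$cube
  sp <- mean_spectra(cal, m, image_id = "scene42")
  out <- withr::local_tempdir()

  man <- write_outputs(sp, out_dir = out)
  expect_identical(man$status, "written")
  csv <- file.path(out, "scene42_spectra.csv")
  back <- read_spectra_csv(csv)
  expect_identical(nrow(back$meta), m$n)
  expect_identical(ncol(back$spectra), n_bands(cal))
  expect_lt(max(abs(back$spectra - sp$spectra) / pmax(abs(sp$spectra), 1e-9)),
            1e-6)
  expect_equal(back$wavelengths, round(sp$wavelengths, 2), tolerance = 1e-8)

  # rerun without overwrite: file untouched
  mt0 <- file.mtime(csv)
  man2 <- write_outputs(sp, out_dir = out)
  expect_identical(man2$status, "skipped")
  expect_identical(file.mtime(csv), mt0)

  # with overwrite: replaced
  man3 <- write_outputs(sp, out_dir = out, overwrite = TRUE)
  expect_identical(man3$status, "written")
})

test_that("per-seed ENVI cubes are written once per seed and re-readable", {
  sc <- cached_scene(rng_seed = 42L)
  m <- segment_scene(sc$raw, segmentation_params(min_pixels = 80L))
  cal <- trim_bands(calibrate(sc$raw, sc$refs))$cube
  sp <- mean_spectra(cal, m, image_id = "scene42")
  cubes <- extract_seed_cubes(cal, m)
  out <- withr::local_tempdir()
  man <- write_outputs(sp, cubes, out_dir = out)
  hdrs <- list.files(file.path(out, "scene42_seeds"), pattern = "\\.hdr$",
                     full.names = TRUE)
  expect_length(hdrs, m$n)
  one <- read_envi(hdrs[1])
  expect_equal(one$data, cubes[[1]]$data, tolerance = 1e-6)  # float32 storage
})
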