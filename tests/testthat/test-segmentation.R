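# Thresholding, labeling, size filtering, hole filling, ellipse
# decomposition and whole-scene segmentation.

test_that("threshold window is strict on both bounds", {
  slice <- matrix(c(400, 1000, 2000, 401, 1999, 0), 2, 3)
  m <- threshold_mask(slice, 400, 2000)
  expect_identical(as.vector(m), c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_false(any(threshold_mask(matrix(0, 3, 3), 400, 2000)))
  expect_error(threshold_mask(slice, 2000, 400), "i_min")
})

test_that("connected components use 8-connectivity", {
  # hand-enumerated 3x3 case: two diagonal pixels form one component
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  lab <- label_components(m)
  expect_identical(max(lab), 1L)

  # two regions separated by a background row
  m2 <- matrix(FALSE, 5, 3); m2[1:2, ] <- TRUE; m2[4:5, ] <- TRUE
  expect_identical(max(label_components(m2)), 2L)

  expect_identical(max(label_components(matrix(FALSE, 4, 4))), 0L)
})

test_that("labels are consecutive and ordered top-most then left-most", {
  m <- matrix(FALSE, 10, 10)
  m[7:9, 1:2] <- TRUE    # lower-left
  m[1:2, 8:9] <- TRUE    # top-right
  m[4:5, 4:5] <- TRUE    # middle
  lab <- label_components(m)
  expect_identical(sort(unique(lab[lab > 0])), 1:3)
  expect_identical(unique(lab[1:2, 8:9])[1], 1L)
  expect_identical(unique(lab[4:5, 4:5])[1], 2L)
  expect_identical(unique(lab[7:9, 1:2])[1], 3L)
})

test_that("size filter removes components strictly below min_pixels", {
  lab <- matrix(0L, 30, 40)
  lab[1:20, 1:25] <- 1L                       # 500 px -> kept
  lab[25:30, 30:40] <- 2L                     # 66 px
  lab[22, 1:30] <- 3L                         # 30 px
  f <- filter_components(lab, min_pixels = 500L)
  expect_identical(max(f), 1L)
  expect_identical(sum(f == 1L), 500L)

  lab499 <- matrix(0L, 30, 40); lab499[1:20, 1:25] <- 1L; lab499[20, 25] <- 0L
  expect_identical(sum(lab499 == 1L), 499L)
  expect_warning(f2 <- filter_components(lab499, 500L), "below min_pixels")
  expect_identical(max(f2), 0L)
})

test_that("hole filling closes enclosed holes and leaves open cavities alone", {
  ring <- matrix(FALSE, 9, 9); ring[3:7, 3:7] <- TRUE; ring[5, 5] <- FALSE
  filled <- fill_holes(ring)
  expect_true(filled[5, 5])
  expect_identical(sum(filled), sum(ring) + 1L)

  solid <- matrix(FALSE, 9, 9); solid[3:7, 3:7] <- TRUE
  expect_identical(fill_holes(solid), solid)

  cshape <- matrix(FALSE, 9, 9); cshape[3:7, 3:7] <- TRUE
  cshape[5, 5] <- FALSE; cshape[5, 6:9] <- FALSE   # cavity opens to the border
  expect_identical(fill_holes(cshape), cshape)
})

test_that("a single planted ellipse is recovered as one ellipse within 10%", {
  m <- seedhsi:::.raster_ellipse(100, 100, cx = 50, cy = 48, a = 30, b = 15,
                                 theta = 0.4)
  dec <- decompose_overlaps(m, max_k = 4L, min_size = 50L, rng_seed = 1L)
  expect_identical(dec$k, 1L)
  e <- dec$ellipses[[1]]
  expect_lt(abs(e$a - 30) / 30, 0.1)
  expect_lt(abs(e$b - 15) / 15, 0.1)
  expect_lt(abs(e$cx - 50), 1)
  expect_lt(abs(e$cy - 48), 1)
})

test_that("two overlapping planted ellipses are split with centers within 3 px", {
  m1 <- seedhsi:::.raster_ellipse(120, 120, 45, 60, 16, 9, 0.2)
  m2 <- seedhsi:::.raster_ellipse(120, 120, 62, 62, 15, 8, 1.3)
  ratio <- sum(m1 & m2) / min(sum(m1), sum(m2))
  expect_gt(ratio, 0.1); expect_lt(ratio, 0.3)
  dec <- decompose_overlaps(m1 | m2, max_k = 4L, min_size = 50L, rng_seed = 1L)
  expect_identical(dec$k, 2L)
  centers <- t(vapply(dec$ellipses, function(e) c(e$cx, e$cy), numeric(2)))
  planted <- rbind(c(45, 60), c(62, 62))
  err <- vapply(seq_len(2), function(i)
    min(sqrt(rowSums(sweep(planted, 2, centers[i, ])^2))), numeric(1))
  expect_true(all(err <= 3))
  # partition invariant: disjoint sub-masks whose union is the component
  inter <- dec$masks[[1]] & dec$masks[[2]]
  expect_false(any(inter))
  expect_identical(dec$masks[[1]] | dec$masks[[2]], m1 | m2)
})

test_that("a disk stays one near-circular ellipse", {
  m <- seedhsi:::.raster_ellipse(80, 80, 40, 40, 18, 18, 0)
  dec <- decompose_overlaps(m, max_k = 4L, min_size = 50L, rng_seed = 2L)
  expect_identical(dec$k, 1L)
  expect_lt(abs(dec$ellipses[[1]]$a - dec$ellipses[[1]]$b) /
            dec$ellipses[[1]]$a, 0.1)
})

test_that("segment_scene recovers planted counts; ellipse fitting splits touching pairs", {
  # 8 separated seeds plus two touching pairs (10 seeds total)
  shapes <- list(
    ellipse(20, 20, 12, 7, 0.3),  ellipse(60, 18, 11, 6, 1.2),
    ellipse(105, 22, 13, 7, 2.0), ellipse(140, 30, 12, 6, 0.8),
    ellipse(25, 70, 11, 7, 1.9),  ellipse(140, 75, 13, 7, 0.1),
    ellipse(30, 125, 12, 6, 2.6), ellipse(130, 130, 11, 7, 1.0),
    # touching pairs
    ellipse(70, 95, 12, 7, 0.0),  ellipse(88, 95, 12, 7, 0.0))
  shapes <- c(shapes, list(ellipse(70, 145, 11, 6, 1.57),
                           ellipse(70, 160, 11, 6, 1.57)))
  cube <- ellipse_scene_cube(shapes)
  params_on <- segmentation_params(band_id = 1L, min_pixels = 80L,
                                   ellipse_fitting = TRUE)
  params_off <- segmentation_params(band_id = 1L, min_pixels = 80L,
                                    ellipse_fitting = FALSE)
  m_on <- segment_scene(cube, params_on)
  m_off <- segment_scene(cube, params_off)
  expect_identical(m_on$n, 12L)
  expect_identical(m_off$n, 10L)   # the two touching pairs stay merged

  # blank scene
  blank <- hypercube(array(0, c(50, 50, 2)), wavelengths = c(600, 700))
  expect_warning(mb <- segment_scene(blank, segmentation_params(band_id = 1L)),
                 "no seeds")
  expect_identical(mb$n, 0L)
})

test_that("raising min_pixels never increases the seed count", {
  sc <- cached_scene(rng_seed = 21L)
  ks <- vapply(c(50L, 150L, 260L, 400L), function(mp)
    suppressWarnings(segment_scene(sc$raw,
                                   segmentation_params(min_pixels = mp)))$n,
    integer(1))   # large thresholds legitimately warn about empty labelings
  expect_true(all(diff(ks) <= 0))
})

test_that("segmentation is deterministic for fixed input and seed", {
  sc <- cached_scene(rng_seed = 22L, overlap_fraction = 0.2)
  p <- segmentation_params(min_pixels = 80L, rng_seed = 5L)
  m1 <- segment_scene(sc$raw, p)
  m2 <- segment_scene(sc$raw, p)
  expect_identical(m1$labels, m2$labels)
  expect_equal(m1$ellipses, m2$ellipses)
})
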