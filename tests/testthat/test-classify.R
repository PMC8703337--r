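# Dataset splits, PCA features, SVMs, sub-cube extraction, majority voting
# and confusion metrics.

# synthetic seed-mean spectra: two groups separated by `gap` above 1000 nm
toy_seed_spectra <- function(n_per_group, n_bands = 50L, gap = 0.05,
                             noise = 0.002, seed = 1L) {
  set.seed(seed)
  wl <- seq(655, 1642, length.out = n_bands)
  cc <- default_group_curves(wl, gap = gap)
  n <- 2L * n_per_group
  groups <- rep(c("control", "hs"), each = n_per_group)
  base <- rbind(matrix(cc$control, n_per_group, n_bands, byrow = TRUE),
                matrix(cc$hs, n_per_group, n_bands, byrow = TRUE))
  list(spectra = base + matrix(rnorm(n * n_bands, sd = noise), n),
       groups = groups, wavelengths = wl)
}

test_that("seed split is stratified 80/20 and pixel partitions conserve pixels", {
  groups <- rep(c("control", "hs"), each = 100L)
  pixel_seed <- rep(seq_len(200L), times = 37L)   # 37 px per seed
  sp <- split_dataset(groups, pixel_seed, rng_seed = 4L)
  expect_length(sp$seed_train, 160L)
  expect_length(sp$seed_test, 40L)
  expect_identical(sum(groups[sp$seed_train] == "hs"), 80L)
  expect_identical(sum(groups[sp$seed_test] == "hs"), 20L)

  total <- length(sp$pixel_train) + length(sp$pixel_val) + length(sp$pixel_test)
  expect_identical(total, length(pixel_seed))
  expect_length(intersect(sp$pixel_train, sp$pixel_val), 0L)
  expect_length(intersect(sp$pixel_train, sp$pixel_test), 0L)
  # pixel test set is exactly the pixels of the test seeds
  expect_setequal(sp$pixel_test, which(pixel_seed %in% sp$seed_test))
  # validation is 5% of the remaining pixels
  expect_identical(length(sp$pixel_val),
                   as.integer(round(0.05 * (total - length(sp$pixel_test)))))

  sp2 <- split_dataset(groups, pixel_seed, rng_seed = 4L)
  expect_identical(sp, sp2)
  expect_error(split_dataset(c("control", "hs"), rng_seed = 1L), "2 seeds")
})

test_that("PCA features are eigen-ordered, centered and train-only", {
  set.seed(8)
  train <- matrix(rnorm(160L * 239L), 160L)
  fit <- seed_svm_features(train, 50L)
  expect_identical(dim(fit$train_scores), c(160L, 50L))
  expect_true(all(diff(apply(fit$train_scores, 2L, var)) <= 1e-8))
  # projecting the training mean -> ~zero vector
  expect_lt(max(abs(project_features(fit, rbind(colMeans(train))))), 1e-10)
  expect_error(seed_svm_features(train, 200L), "n_components")
})

test_that("seed SVM separates well-separated groups and memorizes duplicates", {
  toy <- toy_seed_spectra(50L, gap = 0.05, noise = 0.002)
  sp <- split_dataset(toy$groups, rng_seed = 2L)
  fit <- train_eval_seed_svm(toy$spectra, toy$groups, sp)
  expect_gte(fit$metrics$accuracy, 0.95)
  expect_identical(fit$metrics$seed_group_prediction_accuracy,
                   fit$metrics$accuracy)

  # identical train/test -> perfect memorization
  dup <- sp
  dup$seed_test <- dup$seed_train
  fitd <- train_eval_seed_svm(toy$spectra, toy$groups, dup)
  expect_identical(fitd$metrics$accuracy, 1)

  # shuffled labels -> chance-level accuracy
  set.seed(99)
  shuffled <- sample(toy$groups)
  fits <- train_eval_seed_svm(toy$spectra, shuffled, sp)
  expect_lt(abs(fits$metrics$accuracy - 0.5), 0.25)   # binomial CI at n = 20
})

test_that("pixel SVM predicts every test pixel and rejects one-class input", {
  toy <- toy_seed_spectra(8L, gap = 0.05, noise = 0.004, seed = 3L)
  # fake pixels: 30 per seed
  px_seed <- rep(seq_len(16L), each = 30L)
  px <- list(spectra = toy$spectra[px_seed, ] +
               matrix(rnorm(480L * 50L, sd = 0.004), 480L),
             seed_index = px_seed, group = toy$groups[px_seed],
             wavelengths = toy$wavelengths)
  sp <- split_dataset(toy$groups, px_seed, rng_seed = 5L)
  fit <- train_pixel_svm(px, sp)
  expect_length(fit$predictions, length(sp$pixel_test))
  expect_gte(fit$metrics$accuracy, 0.9)

  one <- px; one$group <- rep("hs", length(one$group))
  expect_error(train_pixel_svm(one, sp), "single-class")
})

test_that("sub-cube extraction yields one padded patch per seed pixel", {
  cube <- const_cube(0.7, ny = 12L, nx = 11L, L = 6L)
  labels <- matrix(0L, 12, 11)
  labels[2:6, 2:6] <- 1L       # touches the frame edge region
  labels[9:11, 8:10] <- 2L
  masks <- seedhsi:::.seed_mask_from_labels(labels)
  sub <- extract_subcubes(cube, masks, S = 5L)
  expect_identical(nrow(sub$patches), sum(labels > 0L))
  expect_identical(ncol(sub$patches), 5L * 5L * 6L)
  # constant cube -> constant patches, including reflected borders
  expect_true(all(sub$patches == 0.7))
  expect_error(extract_subcubes(cube, masks, S = 4L), "odd")
  expect_error(extract_subcubes(cube, masks, S = 25L), "extent")
})

test_that("edge-reflection padding mirrors frame borders", {
  cube <- const_cube(0, ny = 6L, nx = 6L, L = 1L,
                     wavelengths = 1000)
  cube$data[, , 1] <- matrix(seq_len(36), 6, 6)
  labels <- matrix(0L, 6, 6); labels[1L, 1L] <- 1L   # corner pixel
  masks <- seedhsi:::.seed_mask_from_labels(labels)
  sub <- extract_subcubes(cube, masks, S = 3L)
  patch <- matrix(sub$patches[1, ], 3, 3)
  inner <- cube$data[1:2, 1:2, 1]
  expect_identical(patch[2:3, 2:3], inner)
  expect_identical(patch[1, ], patch[2, ])   # reflected row
  expect_identical(patch[, 1], patch[, 2])   # reflected column
})

test_that("majority vote follows the strict-control rule with hs tie-break", {
  pred <- c(rep("control", 6L), rep("hs", 4L),     # seed 1: 60% control
            rep("hs", 5L),                         # seed 2: all hs
            rep("control", 3L), rep("hs", 3L))     # seed 3: exact tie
  seeds <- c(rep(1L, 10L), rep(2L, 5L), rep(3L, 6L))
  v <- vote_seed_labels(pred, seeds)
  expect_identical(unname(v), c("control", "hs", "hs"))

  # invariant to pixel ordering
  set.seed(1); perm <- sample(length(pred))
  expect_identical(vote_seed_labels(pred[perm], seeds[perm]), v)
  expect_error(vote_seed_labels(pred, seeds[-1]), "lengths")
})

test_that("confusion metrics reproduce the four-metric identity set", {
  # derived example: the unique non-negative counts behind an 80% / 78.94%
  # accuracy/F pair on 40 samples
  truth <- c(rep("hs", 18L), rep("control", 22L))
  pred <- c(rep("hs", 15L), rep("control", 3L),
            rep("hs", 5L), rep("control", 17L))
  m <- confusion_metrics(truth, pred)
  expect_identical(c(m$tp, m$tn, m$fp, m$fn), c(15L, 17L, 5L, 3L))
  expect_equal(100 * m$accuracy, 80.00, tolerance = 1e-10)
  expect_equal(100 * m$precision, 75.00, tolerance = 1e-10)
  expect_equal(100 * m$recall, 83.33, tolerance = 0.005)
  expect_equal(100 * m$f_score, 78.94, tolerance = 0.01)

  perfect <- confusion_metrics(truth, truth)
  expect_identical(c(perfect$accuracy, perfect$precision, perfect$recall,
                     perfect$f_score), c(1, 1, 1, 1))

  m2 <- confusion_metrics(c("hs", "control"), c("hs", "hs"))
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$recall, 1)
  expect_equal(m2$f_score, 2 / 3)
  expect_error(confusion_metrics(character(0), character(0)), "empty")
})

test_that("F-score equals the harmonic mean of precision and recall", {
  set.seed(12)
  for (i in 1:20) {
    truth <- sample(c("control", "hs"), 30L, replace = TRUE)
    pred <- sample(c("control", "hs"), 30L, replace = TRUE)
    m <- confusion_metrics(truth, pred)
    if (!is.na(m$precision) && !is.na(m$recall) &&
        (m$precision + m$recall) > 0) {
      expect_equal(m$f_score,
                   2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-12)
    }
  }
})
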