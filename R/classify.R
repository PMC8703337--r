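# Seed-group classification: dataset splits, seed-level SVM on PCA features,
# pixel-level SVM, majority voting of pixel calls to seed calls, and the
# confusion-matrix metrics. The heat-stress (hs) group is the positive class
# throughout.

#' Assemble a per-pixel dataset from a segmented cube
#'
#' Flattens every seed pixel into one row of spectra, carrying its seed index
#' and coordinates; group labels are attached per seed.
#'
#' @param cube a \code{\link{hypercube}} (typically calibrated + trimmed).
#' @param masks a \code{seed_mask} (or any object with a \code{labels} matrix).
#' @param groups character vector of per-seed group labels
#'   (\code{"control"}/\code{"hs"}), one per seed.
#' @return list with \code{spectra} (pixels x bands), \code{seed_index},
#'   \code{group} (per pixel), \code{x}, \code{y}, \code{wavelengths}.
#' @export
pixel_dataset <- function(cube, masks, groups) {
  labels <- masks$labels
  d <- dim(cube$data)
  stopifnot(all(dim(labels) == d[1:2]))
  k <- max(labels, 0L)
  if (length(groups) != k)
    stop("need one group label per seed (", k, " seeds)")
  idx <- which(labels > 0L)
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])
  seed_index <- labels[idx]
  list(spectra = flat[idx, , drop = FALSE],
       seed_index = seed_index,
       group = groups[seed_index],
       x = col(labels)[idx], y = row(labels)[idx],
       wavelengths = cube$wavelengths)
}

#' Split seeds and pixels into train/validation/test sets
#'
#' Seeds are split 80/20 stratified by group. The pixel-level test set is
#' exactly the pixels of the test seeds; the remaining pixels are split 95/5
#' into training and validation. No pixel appears in two partitions.
#' Reproducible from \code{rng_seed}.
#'
#' @param seed_groups per-seed group labels.
#' @param pixel_seed_index per-pixel owning-seed index (may be \code{NULL}
#'   for a seed-only split).
#' @param seed_train_frac fraction of seeds per group used for training.
#' @param pixel_val_frac fraction of the non-test pixels held out for
#'   validation.
#' @param rng_seed integer seed.
#' @return object of class \code{"dataset_split"}: \code{seed_train},
#'   \code{seed_test} (seed indices), and if pixels were given
#'   \code{pixel_train}, \code{pixel_val}, \code{pixel_test} (row indices).
#' @export
split_dataset <- function(seed_groups, pixel_seed_index = NULL,
                          seed_train_frac = 0.8, pixel_val_frac = 0.05,
                          rng_seed = 1L) {
  groups <- unique(seed_groups)
  if (any(table(seed_groups) < 2L))
    stop("each group needs >= 2 seeds to stratify")
  with_rng_seed(rng_seed, {
    seed_train <- integer(0)
    for (g in groups) {
      ids <- which(seed_groups == g)
      n_tr <- round(seed_train_frac * length(ids))
      seed_train <- c(seed_train, sort(sample(ids, n_tr)))
    }
    seed_train <- sort(seed_train)
    seed_test <- setdiff(seq_along(seed_groups), seed_train)
    out <- list(seed_train = seed_train, seed_test = seed_test)
    if (!is.null(pixel_seed_index)) {
      pixel_test <- which(pixel_seed_index %in% seed_test)
      rest <- which(pixel_seed_index %in% seed_train)
      n_val <- round(pixel_val_frac * length(rest))
      pixel_val <- sort(sample(rest, n_val))
      out$pixel_train <- setdiff(rest, pixel_val)
      out$pixel_val <- pixel_val
      out$pixel_test <- pixel_test
    }
    structure(out, class = "dataset_split")
  })
}

#' PCA features for the seed-level SVM
#'
#' Principal components are fit on the training spectra only (centering on
#' the training mean, no scaling — reflectance is already on a common scale)
#' and ranked by eigenvalue; any spectra can then be projected with the same
#' transform via \code{\link{project_features}}.
#'
#' @param train_spectra training matrix (seeds x bands).
#' @param n_components number of components kept (defaults to 50, capped at
#'   what the data supports).
#' @return list with \code{center}, \code{rotation} (bands x components) and
#'   \code{train_scores}.
#' @export
seed_svm_features <- function(train_spectra, n_components = 50L) {
  max_nc <- min(nrow(train_spectra) - 1L, ncol(train_spectra))
  if (n_components > max_nc)
    stop(sprintf("n_components (%d) exceeds min(n_train - 1, n_bands) = %d",
                 n_components, max_nc))
  pc <- stats::prcomp(train_spectra, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  list(center = pc$center, rotation = rot,
       train_scores = pc$x[, seq_len(n_components), drop = FALSE],
       sdev = pc$sdev[seq_len(n_components)])
}

#' Project spectra with a fitted PCA transform
#' @param fit result of \code{\link{seed_svm_features}}.
#' @param spectra matrix (rows x bands).
#' @return score matrix (rows x components).
#' @export
project_features <- function(fit, spectra) {
  sweep(spectra, 2L, fit$center) %*% fit$rotation
}

# gamma as 1/(n_features * variance of the training matrix)
.rbf_gamma <- function(x) {
  v <- stats::var(as.vector(x))
  if (v <= 0) v <- 1
  1 / (ncol(x) * v)
}

.fit_rbf_svm <- function(train_x, train_y, cost = 1) {
  y <- factor(train_y, levels = c("control", "hs"))
  if (length(unique(train_y)) < 2L)
    stop("degenerate single-class training set")
  e1071::svm(train_x, y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = .rbf_gamma(train_x), scale = FALSE)
}

#' Train and evaluate the seed-level SVM
#'
#' Fits an RBF-kernel SVM on the PCA features of the training seeds' mean
#' spectra and evaluates on the test seeds. One seed is one sample, so the
#' seed-group prediction accuracy equals the test accuracy.
#'
#' @param spectra seeds x bands matrix of mean reflectance.
#' @param seed_groups per-seed group labels.
#' @param split a \code{\link{split_dataset}} result.
#' @param n_components PCA components (default 50, capped at what the
#'   training set supports).
#' @param cost SVM cost parameter.
#' @return list with \code{metrics} (a \code{metrics_report}),
#'   \code{predictions} (named by test seed), \code{pca}, \code{model}.
#' @export
train_eval_seed_svm <- function(spectra, seed_groups, split,
                                n_components = 50L, cost = 1) {
  nc <- min(n_components, nrow(spectra[split$seed_train, , drop = FALSE]) - 1L,
            ncol(spectra))
  pca <- seed_svm_features(spectra[split$seed_train, , drop = FALSE], nc)
  model <- .fit_rbf_svm(pca$train_scores, seed_groups[split$seed_train], cost)
  test_scores <- project_features(pca, spectra[split$seed_test, , drop = FALSE])
  pred <- as.character(stats::predict(model, test_scores))
  names(pred) <- split$seed_test
  metrics <- confusion_metrics(seed_groups[split$seed_test], pred)
  metrics$seed_group_prediction_accuracy <- metrics$accuracy
  list(metrics = metrics, predictions = pred, pca = pca, model = model)
}

#' Train the pixel-level SVM and predict test pixels
#'
#' An RBF-kernel SVM on single-pixel spectra (no spatial context). With many
#' training pixels a random subsample caps the kernel problem size; the
#' default keeps every pixel at desk scale.
#'
#' @param pixels result of \code{\link{pixel_dataset}}.
#' @param split a \code{\link{split_dataset}} result with pixel partitions.
#' @param cost SVM cost parameter.
#' @param max_train_pixels cap on training pixels (subsampled, seeded).
#' @param rng_seed seed for the subsample.
#' @return list with \code{predictions} (character, one per test pixel, in
#'   \code{split$pixel_test} order), \code{metrics} (pixel-level), and
#'   \code{model}.
#' @export
train_pixel_svm <- function(pixels, split, cost = 1,
                            max_train_pixels = 20000L, rng_seed = 1L) {
  tr <- split$pixel_train
  if (length(tr) > max_train_pixels)
    tr <- with_rng_seed(rng_seed, sort(sample(tr, max_train_pixels)))
  model <- .fit_rbf_svm(pixels$spectra[tr, , drop = FALSE], pixels$group[tr],
                        cost)
  pred <- as.character(stats::predict(
    model, pixels$spectra[split$pixel_test, , drop = FALSE]))
  metrics <- confusion_metrics(pixels$group[split$pixel_test], pred)
  list(predictions = pred, metrics = metrics, model = model)
}

#' Extract S x S x L sub-cube patches around every seed pixel
#'
#' One sample per seed pixel: the S x S spatial neighborhood with the full
#' retained spectrum, labeled by the center pixel's seed. Patches reaching
#' past the frame are completed by edge-reflection padding, keeping the
#' one-sample-per-pixel count exact.
#'
#' @param cube a \code{\link{hypercube}} (calibrated + trimmed).
#' @param masks a \code{seed_mask}.
#' @param S odd spatial patch size (default 5).
#' @return list with \code{patches} (pixels x \code{S*S*L} matrix, fastest
#'   axis y within the patch, then x, then band), \code{seed_index},
#'   \code{x}, \code{y}, \code{S}, \code{n_bands}.
#' @export
extract_subcubes <- function(cube, masks, S = 5L) {
  if (S %% 2L == 0L) stop("S must be odd")
  d <- dim(cube$data)
  if (S > d[1L] || S > d[2L]) stop("S larger than image extent")
  r <- (S - 1L) %/% 2L
  # symmetric (edge-reflecting) index vectors
  ry <- c(r:1, seq_len(d[1L]), d[1L]:(d[1L] - r + 1L))[seq_len(d[1L] + 2L * r)]
  rx <- c(r:1, seq_len(d[2L]), d[2L]:(d[2L] - r + 1L))[seq_len(d[2L] + 2L * r)]
  padded <- cube$data[ry, rx, , drop = FALSE]
  idx <- which(masks$labels > 0L)
  yy <- row(masks$labels)[idx]; xx <- col(masks$labels)[idx]
  n <- length(idx)
  py <- dim(padded)[1L]
  offs <- as.vector(outer(seq_len(S) - 1L,
                          (seq_len(S) - 1L) * py, "+"))          # S*S offsets
  plane <- py * dim(padded)[2L]
  band_offs <- (seq_len(d[3L]) - 1L) * plane
  base <- (xx - 1L) * py + yy                                    # padded top-left
  cell <- outer(offs, band_offs, "+")                            # S*S x L
  patches <- matrix(padded[outer(base, as.vector(cell), "+")], n)
  list(patches = patches, seed_index = masks$labels[idx],
       x = xx, y = yy, S = S, n_bands = d[3L])
}

#' Aggregate per-pixel predictions to per-seed labels by majority vote
#'
#' A seed is called control if strictly more than half of its predicted
#' pixels are control; otherwise (including an exact tie) it is called hs.
#'
#' @param predictions character vector of per-pixel predictions.
#' @param seed_index per-pixel owning-seed index, same length.
#' @return named character vector of per-seed labels.
#' @export
vote_seed_labels <- function(predictions, seed_index) {
  if (length(predictions) != length(seed_index))
    stop("predictions and seed_index lengths differ")
  seeds <- sort(unique(seed_index))
  out <- vapply(seeds, function(s) {
    p <- predictions[seed_index == s]
    if (length(p) == 0L) stop("seed ", s, " has no predicted pixels")
    if (sum(p == "control") > length(p) / 2) "control" else "hs"
  }, character(1))
  names(out) <- seeds
  out
}

#' Confusion counts and classification metrics
#'
#' Computes TP/TN/FP/FN with hs as the positive class and the four standard
#' metrics:
#' \deqn{Accuracy = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{Precision = TP/(TP+FP),\quad Recall = TP/(TP+FN)}
#' \deqn{F = 2TP/(2TP+FP+FN)}
#'
#' @param truth,predictions equal-length label vectors
#'   (\code{"control"}/\code{"hs"}).
#' @param positive positive-class label.
#' @return object of class \code{"metrics_report"} with \code{tp}, \code{tn},
#'   \code{fp}, \code{fn}, \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f_score} (proportions in [0, 1]; \code{NA} where the denominator
#'   is zero).
#' @export
confusion_metrics <- function(truth, predictions, positive = "hs") {
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(predictions))
    stop("truth and predictions lengths differ")
  tp <- sum(truth == positive & predictions == positive)
  tn <- sum(truth != positive & predictions != positive)
  fp <- sum(truth != positive & predictions == positive)
  fn <- sum(truth == positive & predictions != positive)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = div(tp + tn, tp + tn + fp + fn),
                 precision = div(tp, tp + fp),
                 recall = div(tp, tp + fn),
                 f_score = div(2 * tp, 2 * tp + fp + fn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics> TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F %.2f%%\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$recall,
              100 * x$f_score))
  if (!is.null(x$seed_group_prediction_accuracy))
    cat(sprintf("  seed-group prediction accuracy %.2f%%\n",
                100 * x$seed_group_prediction_accuracy))
  invisible(x)
}

#' Run all three classifiers on one synthetic scene
#'
#' Convenience benchmark: segments the raw cube, calibrates and trims,
#' assigns group labels by matching recovered seeds to the planted truth,
#' splits seeds 80/20 (pixels 95/5 train/validation), then trains and
#' evaluates the seed-level SVM, the pixel-level SVM and the 3D CNN, voting
#' pixel predictions to seed calls.
#'
#' @param scene result of \code{\link{generate_scene}}.
#' @param seg a \code{\link{segmentation_params}}.
#' @param rng_seed seed for the split and model training.
#' @param epochs CNN epoch cap.
#' @return data frame with one row per model (\code{seed_svm},
#'   \code{pixel_svm}, \code{cnn3d}): pixel-level accuracy (\code{NA} for the
#'   seed SVM) and seed-level accuracy.
#' @export
benchmark_classifiers <- function(scene, seg = segmentation_params(min_pixels = 80L),
                                  rng_seed = 1L, epochs = 20L) {
  masks <- segment_scene(scene$raw, seg)
  cal <- trim_bands(calibrate(scene$raw, scene$refs))$cube
  matched <- match_truth(masks, scene$truth)
  grp <- matched$group
  spectra <- mean_spectra(cal, masks)
  px <- pixel_dataset(cal, masks, grp)
  split <- split_dataset(grp, px$seed_index, rng_seed = rng_seed)
  test_groups <- grp[split$seed_test]

  s1 <- train_eval_seed_svm(spectra$spectra, grp, split)

  s2 <- train_pixel_svm(px, split, rng_seed = rng_seed)
  v2 <- vote_seed_labels(s2$predictions, px$seed_index[split$pixel_test])
  acc2 <- mean(v2 == grp[as.integer(names(v2))])

  sub <- extract_subcubes(cal, masks, S = 5L)
  pg <- grp[sub$seed_index]
  net <- cnn3d_train(sub$patches[split$pixel_train, , drop = FALSE],
                     pg[split$pixel_train],
                     sub$patches[split$pixel_val, , drop = FALSE],
                     pg[split$pixel_val],
                     S = 5L, L = n_bands(cal), epochs = epochs,
                     rng_seed = rng_seed)
  pr <- predict(net, sub$patches[split$pixel_test, , drop = FALSE])
  pred3 <- ifelse(pr[, "hs"] > 0.5, "hs", "control")
  m3 <- confusion_metrics(pg[split$pixel_test], pred3)
  v3 <- vote_seed_labels(pred3, px$seed_index[split$pixel_test])
  acc3 <- mean(v3 == grp[as.integer(names(v3))])

  data.frame(
    model = c("seed_svm", "pixel_svm", "cnn3d"),
    pixel_accuracy = c(NA_real_, s2$metrics$accuracy, m3$accuracy),
    seed_accuracy = c(s1$metrics$seed_group_prediction_accuracy, acc2, acc3))
}
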