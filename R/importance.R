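# Wavelength importance from a leaf-wise gradient-boosted tree ensemble:
# each wavelength is one feature, importance is the number of tree splits
# using it, normalized by the total split count.

#' Rank wavelengths by split-count importance
#'
#' Trains a gradient-boosted decision-tree ensemble with leaf-wise growth
#' under a depth constraint (xgboost, \code{grow_policy = "lossguide"}) on
#' pixel spectra vs group labels, then scores each wavelength by the number
#' of times it is used to split, divided by the total number of splits, so
#' the importances form a probability vector. Ranks sort importance
#' descending, ties broken by ascending wavelength.
#'
#' @param spectra pixels x bands matrix.
#' @param labels per-pixel group labels (\code{"control"}/\code{"hs"}).
#' @param wavelengths band-center wavelengths (nm), one per column.
#' @param n_trees,n_leaves,max_depth,learning_rate ensemble parameters.
#' @param metric \code{"split"} (the default, split counts) or \code{"gain"}.
#' @param top_n rows reported by the print method.
#' @param rng_seed seed passed to the booster.
#' @return object of class \code{"band_importance"}: data frame with columns
#'   \code{wavelength_nm}, \code{importance}, \code{rank}, ordered by rank;
#'   attributes carry the parameters.
#' @export
rank_band_importance <- function(spectra, labels, wavelengths,
                                 n_trees = 200L, n_leaves = 31L,
                                 max_depth = 8L, learning_rate = 0.1,
                                 metric = c("split", "gain"), top_n = 12L,
                                 rng_seed = 1L) {
  metric <- match.arg(metric)
  if (length(unique(labels)) < 2L) stop("need >= 2 classes")
  if (length(wavelengths) != ncol(spectra))
    stop("one wavelength per spectral column required")
  y <- as.integer(labels == "hs")
  feat_names <- sprintf("wl_%d", seq_along(wavelengths))
  x <- as.matrix(spectra)
  colnames(x) <- feat_names
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", tree_method = "hist",
                  grow_policy = "lossguide", max_leaves = n_leaves,
                  max_depth = max_depth, eta = learning_rate,
                  nthread = 1L, seed = rng_seed),
    data = dtrain, nrounds = n_trees, verbose = 0)
  imp <- xgboost::xgb.importance(model = booster)
  if (nrow(imp) == 0L) stop("ensemble made zero splits")
  score <- stats::setNames(rep(0, length(wavelengths)), feat_names)
  col <- if (metric == "split") "Frequency" else "Gain"
  score[imp$Feature] <- imp[[col]]
  score <- score / sum(score)
  ord <- order(-score, wavelengths)
  out <- data.frame(wavelength_nm = wavelengths[ord],
                    importance = unname(score[ord]),
                    rank = seq_along(wavelengths))
  structure(out, class = c("band_importance", "data.frame"),
            metric = metric, top_n = top_n,
            params = list(n_trees = n_trees, n_leaves = n_leaves,
                          max_depth = max_depth,
                          learning_rate = learning_rate,
                          rng_seed = rng_seed))
}

#' @export
print.band_importance <- function(x, ...) {
  top_n <- min(attr(x, "top_n"), nrow(x))
  cat(sprintf("<band_importance> %d wavelengths, %s-count metric; top %d:\n",
              nrow(x), attr(x, "metric"), top_n))
  print.data.frame(utils::head(as.data.frame(x), top_n), row.names = FALSE)
  invisible(x)
}

#' @export
plot.band_importance <- function(x, top_n = NULL, ...) {
  if (is.null(top_n)) top_n <- attr(x, "top_n")
  top <- utils::head(as.data.frame(x), top_n)
  graphics::barplot(rev(top$importance),
                    names.arg = sprintf("%.0f", rev(top$wavelength_nm)),
                    horiz = TRUE, las = 1, xlab = "normalized importance",
                    ylab = "wavelength (nm)", ...)
  invisible(x)
}
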