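# Per-seed segmentation of a band slice: intensity window -> connected
# components -> minimum-size filter -> hole filling -> optional decomposition
# of merged components into ellipses.

#' Segmentation parameter set
#'
#' Mirrors the batch tool's segmentation controls. \code{band_id} is the
#' 1-based band whose slice is segmented (band 20 gives good seed/background
#' contrast on a black platform with the default spectral grid);
#' \code{i_min}/\code{i_max} bound the intensity window (strict inequalities);
#' \code{min_pixels} is the smallest component kept as a seed.
#'
#' @param band_id 1-based band index.
#' @param i_min,i_max intensity window; a pixel is foreground iff
#'   \code{i_min < I < i_max}.
#' @param min_pixels minimum component pixel count.
#' @param ellipse_fitting decompose merged components into ellipses?
#' @param max_ellipses maximum ellipses fitted per component.
#' @param rng_seed seed for the ellipse-fit initialization.
#' @return an object of class \code{"segmentation_params"}.
#' @export
segmentation_params <- function(band_id = 20L, i_min = 400, i_max = 2000,
                                min_pixels = 500L, ellipse_fitting = TRUE,
                                max_ellipses = 6L, rng_seed = 1L) {
  if (i_min >= i_max) stop("i_min must be < i_max")
  if (min_pixels < 1L) stop("min_pixels must be >= 1")
  if (band_id < 1L) stop("band_id must be >= 1")
  structure(list(band_id = as.integer(band_id), i_min = i_min, i_max = i_max,
                 min_pixels = as.integer(min_pixels),
                 ellipse_fitting = isTRUE(ellipse_fitting),
                 max_ellipses = as.integer(max_ellipses),
                 rng_seed = as.integer(rng_seed)),
            class = "segmentation_params")
}

#' Threshold a band slice into a foreground mask
#'
#' A pixel with intensity \eqn{I} is kept iff \eqn{I_{min} < I < I_{max}}
#' (both inequalities strict). The upper bound removes specular highlights
#' and the white tile; the lower bound removes the black platform.
#'
#' @param slice numeric matrix \code{[y, x]}.
#' @param i_min,i_max window bounds.
#' @return logical matrix, \code{TRUE} = foreground.
#' @export
threshold_mask <- function(slice, i_min = 400, i_max = 2000) {
  if (i_min >= i_max) stop("i_min must be < i_max")
  slice > i_min & slice < i_max
}

#' Label connected foreground components (8-connectivity)
#'
#' Maximal 8-connected regions are labeled 1..K; background stays 0. Labels
#' are ordered by the component bounding box: top-most first, ties broken by
#' left-most.
#'
#' @param mask logical or 0/1 matrix \code{[y, x]}.
#' @return integer label matrix of the same shape.
#' @export
label_components <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)            # 4-connected labeling
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  k <- max(lab)
  if (k > 1L) {
    # merge labels that touch diagonally to obtain 8-connectivity
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
    ny <- nrow(lab); nx <- ncol(lab)
    a1 <- lab[-ny, -nx]; b1 <- lab[-1L, -1L]    # down-right diagonal
    a2 <- lab[-1L, -nx]; b2 <- lab[-ny, -1L]    # up-right diagonal
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- unique(pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                          pairs[, 1L] != pairs[, 2L], , drop = FALSE])
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(k), find, integer(1))
    lab[lab > 0L] <- roots[lab[lab > 0L]]
  }
  relabel_components(lab)
}

#' Relabel components consecutively in reading order
#'
#' Survivor labels are renumbered 1..K ordered by (top-most, then left-most)
#' bounding-box corner.
#'
#' @param labels integer label matrix.
#' @return integer label matrix with consecutive labels.
#' @export
relabel_components <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(labels)
  top  <- vapply(ids, function(i) min(row(labels)[labels == i]), numeric(1))
  left <- vapply(ids, function(i) min(col(labels)[labels == i]), numeric(1))
  ord <- ids[order(top, left)]
  out <- labels
  for (j in seq_along(ord)) out[labels == ord[j]] <- j
  out
}

#' Remove components smaller than a pixel threshold
#'
#' Components with \emph{fewer than} \code{min_pixels} pixels are deleted
#' (strict: a component of exactly \code{min_pixels} survives); survivors are
#' relabeled consecutively.
#'
#' @param labels integer label matrix.
#' @param min_pixels minimum pixel count.
#' @return integer label matrix.
#' @export
filter_components <- function(labels, min_pixels = 500L) {
  tab <- tabulate(labels[labels > 0L])
  drop <- which(tab < min_pixels & tab > 0L)
  out <- labels
  out[out %in% drop] <- 0L
  if (all(out == 0L) && any(labels > 0L))
    warning("all components below min_pixels = ", min_pixels)
  relabel_components(out)
}

#' Fill enclosed holes in a binary mask
#'
#' Background pixels not connected to the image border are converted to
#' foreground; open cavities (reachable from outside) are left alone.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- EBImage::fillHull(m)
  matrix(as.integer(out) > 0L, nrow(mask), ncol(mask))
}

# --- ellipse mixture decomposition -----------------------------------------

# squared Mahalanobis distances of points (n x 2) to one Gaussian component
.mahal2 <- function(pts, mu, sigma) {
  ch <- chol(sigma)
  z <- backsolve(ch, t(pts) - mu, transpose = TRUE)
  colSums(z^2)
}

# k-means++ seeding on pixel coordinates (deterministic under set.seed)
.kmeanspp <- function(pts, k) {
  n <- nrow(pts)
  centers <- matrix(NA_real_, k, 2L)
  centers[1L, ] <- pts[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums((pts - matrix(centers[1L, ], n, 2L, byrow = TRUE))^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      centers[j, ] <- pts[sample.int(n, 1L, prob = p), ]
      nd2 <- rowSums((pts - matrix(centers[j, ], n, 2L, byrow = TRUE))^2)
      d2 <- pmin(d2, nd2)
    }
  }
  centers
}

# Full-covariance 2-D Gaussian mixture via EM. Returns means, covariances,
# weights, responsibilities and the final log-likelihood.
.fit_gmm <- function(pts, k, tol = 1e-4, max_iter = 200L, ridge = 1e-2,
                     centers = NULL) {
  n <- nrow(pts)
  if (is.null(centers)) centers <- .kmeanspp(pts, k)
  assign0 <- max.col(-vapply(seq_len(k), function(j)
    rowSums((pts - matrix(centers[j, ], n, 2L, byrow = TRUE))^2), numeric(n)))
  mu <- lapply(seq_len(k), function(j) {
    idx <- which(assign0 == j)
    if (length(idx) == 0L) centers[j, ] else colMeans(pts[idx, , drop = FALSE])
  })
  sigma <- lapply(seq_len(k), function(j) {
    idx <- which(assign0 == j)
    s <- if (length(idx) > 2L) stats::cov(pts[idx, , drop = FALSE]) else diag(2)
    s + diag(ridge, 2L)
  })
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logp <- vapply(seq_len(k), function(j) {
      ch <- chol(sigma[[j]])
      -0.5 * .mahal2(pts, mu[[j]], sigma[[j]]) - sum(log(diag(ch))) -
        log(2 * pi) + log(w[j])
    }, numeric(n))
    mx <- apply(logp, 1L, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    ll <- sum(lse)
    resp <- exp(logp - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) break   # collapsed component; keep previous params
    w <- nk / n
    for (j in seq_len(k)) {
      mu[[j]] <- colSums(resp[, j] * pts) / nk[j]
      d <- pts - matrix(mu[[j]], n, 2L, byrow = TRUE)
      sigma[[j]] <- crossprod(d * sqrt(resp[, j])) / nk[j] + diag(ridge, 2L)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) { ll_old <- ll; break }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, w = w, loglik = ll_old,
       resp = resp)
}

# Ellipse parameters from a cluster's covariance, scaled so the ellipse area
# matches the cluster pixel count (for a uniformly filled ellipse the
# covariance eigenvalues are a^2/4 and b^2/4, so the scale recovers the axes).
.cov_to_ellipse <- function(mu, sigma, npix) {
  e <- eigen(sigma, symmetric = TRUE)
  s1 <- sqrt(max(e$values[1L], 1e-12))
  s2 <- sqrt(max(e$values[2L], 1e-12))
  cc <- sqrt(npix / (pi * s1 * s2))
  theta <- atan2(e$vectors[2L, 1L], e$vectors[1L, 1L])
  if (theta < 0) theta <- theta + pi
  if (theta >= pi) theta <- theta - pi
  structure(list(cx = mu[1L], cy = mu[2L], a = cc * s1, b = cc * s2,
                 theta = theta), class = "ellipse_params")
}

# Bernoulli coverage score of a k-ellipse decomposition: rasterize the union
# of the fitted ellipses over the component's padded bounding box and compare
# with the actual region. With mismatch rate eps over N box pixels the
# deviance is 2 N H(eps); each ellipse costs a BIC-style 5 log N (center,
# axes, orientation). Lower is better.
.coverage_score <- function(mask, ellipses, k) {
  rows <- range(row(mask)[mask]); cols <- range(col(mask)[mask])
  r0 <- max(1L, rows[1L] - 3L); r1 <- min(nrow(mask), rows[2L] + 3L)
  c0 <- max(1L, cols[1L] - 3L); c1 <- min(ncol(mask), cols[2L] + 3L)
  region <- mask[r0:r1, c0:c1]
  xs <- matrix(seq(c0, c1), nrow(region), ncol(region), byrow = TRUE)
  ys <- matrix(seq(r0, r1), nrow(region), ncol(region))
  un <- matrix(FALSE, nrow(region), ncol(region))
  for (e in ellipses) {
    u <- (xs - e$cx) * cos(e$theta) + (ys - e$cy) * sin(e$theta)
    v <- -(xs - e$cx) * sin(e$theta) + (ys - e$cy) * cos(e$theta)
    un <- un | ((u / e$a)^2 + (v / e$b)^2 <= 1)
  }
  mismatch <- sum(un != region)
  # an extra ellipse must explain at least ~3% of the component area
  mismatch + 0.03 * sum(region) * k
}

# Hard-assign pixels to mixture components by Mahalanobis distance (ties to
# the lower index). Ellipse parameters come from the EM mixture itself: soft
# responsibilities keep the centers of overlapping seeds unbiased, with the
# ellipse area matched to each component expected pixel share.
.assign_and_fit <- function(pts, fit, k) {
  n <- nrow(pts)
  if (k == 1L) {
    mu <- colMeans(pts)
    sg <- stats::cov(pts) + diag(1e-2, 2L)
    return(list(assign = rep(1L, n), ellipses = list(.cov_to_ellipse(mu, sg, n))))
  }
  d2 <- vapply(seq_len(k), function(j) .mahal2(pts, fit$mu[[j]], fit$sigma[[j]]),
               numeric(n))
  hard <- max.col(-d2, ties.method = "first")
  ellipses <- lapply(seq_len(k), function(j)
    .cov_to_ellipse(fit$mu[[j]], fit$sigma[[j]], fit$w[j] * n))
  list(assign = hard, ellipses = ellipses)
}

#' Decompose a merged component into ellipse-shaped seeds
#'
#' Touching seeds survive connected-component labeling as one region. For
#' each candidate count \eqn{k = 1..max_k} this routine fits a k-component
#' Gaussian mixture to the region's pixel coordinates (EM, k-means++
#' initialization), converts each cluster to the ellipse whose covariance
#' contour matches the cluster's pixel count, and scores the candidate by a
#' penalized coverage criterion: the pixel mismatch between the region and
#' the union of the candidate ellipses (a Bernoulli coverage
#' log-likelihood up to scale), plus a per-ellipse penalty of 5% of the
#' component area. The minimizing k wins. Pixels are
#' assigned to the nearest ellipse in Mahalanobis distance (ties to the
#' lower seed index), so the sub-masks are disjoint and partition the
#' region.
#'
#' Candidate splits that would produce a cluster smaller than \code{min_size}
#' pixels are rejected: they could not survive downstream size filtering.
#'
#' @param mask logical matrix containing a single filled component.
#' @param max_k maximum number of ellipses.
#' @param min_size smallest admissible sub-component, in pixels.
#' @param rng_seed seed for the k-means++ initialization.
#' @return list with elements \code{k}, \code{ellipses} (list of
#'   \code{ellipse_params}: center \code{cx}, \code{cy}; semi-axes \code{a >=
#'   b}; orientation \code{theta} in \code{[0, pi)}) and \code{masks} (list of
#'   disjoint logical matrices whose union is \code{mask}).
#' @export
decompose_overlaps <- function(mask, max_k = 6L, min_size = 1L, rng_seed = 1L) {
  idx <- which(mask)
  pts <- cbind(x = as.numeric(col(mask)[idx]), y = as.numeric(row(mask)[idx]))
  n <- nrow(pts)
  single <- function() {
    mu <- colMeans(pts)
    sg <- stats::cov(pts) + diag(1e-2, 2L)
    list(k = 1L, ellipses = list(.cov_to_ellipse(mu, sg, n)),
         masks = list(mask))
  }
  if (n < max(20L, 2L * min_size) || max_k <= 1L) return(single())
  cands <- vector("list", max_k)
  score <- rep(Inf, max_k)
  n_restarts <- 3L
  # deterministic initialization: equal-count split along the principal axis
  # (ideal for chains of touching ellipses), tried alongside random restarts
  pc1 <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 1L]
  proj <- as.vector(pts %*% pc1)
  axis_centers <- function(k) {
    qs <- stats::quantile(proj, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    grp <- findInterval(proj, stats::quantile(proj, probs = seq_len(k - 1) / k,
                                              names = FALSE)) + 1L
    t(vapply(seq_len(k), function(j) colMeans(pts[grp == j, , drop = FALSE]),
             numeric(2L)))
  }
  with_rng_seed(rng_seed, {
    for (k in seq_len(max_k)) {
      inits <- if (k == 1L) list(NULL) else
        c(list(axis_centers(k)), replicate(n_restarts, NULL, simplify = FALSE))
      for (init in inits) {
        fit <- tryCatch(.fit_gmm(pts, k, centers = init),
                        error = function(e) NULL)
        if (is.null(fit) || !is.finite(fit$loglik)) next
        cand <- .assign_and_fit(pts, fit, k)
        if (is.null(cand)) next
        if (any(tabulate(cand$assign, k) < min_size)) next
        sc <- .coverage_score(mask, cand$ellipses, k)
        if (sc < score[k]) { cands[[k]] <- cand; score[k] <- sc }
      }
    }
  })
  if (all(!is.finite(score))) return(single())
  kstar <- which.min(score)
  cand <- cands[[kstar]]
  if (kstar == 1L)
    return(list(k = 1L, ellipses = cand$ellipses, masks = list(mask)))
  masks <- vector("list", kstar)
  for (j in seq_len(kstar)) {
    mj <- matrix(FALSE, nrow(mask), ncol(mask))
    mj[idx[cand$assign == j]] <- TRUE
    masks[[j]] <- mj
  }
  ellipses <- cand$ellipses
  # order sub-seeds by (top-most, left-most) of their bounding boxes
  top  <- vapply(masks, function(m) min(row(m)[m]), numeric(1))
  left <- vapply(masks, function(m) min(col(m)[m]), numeric(1))
  ord <- order(top, left)
  list(k = kstar, ellipses = ellipses[ord], masks = masks[ord])
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("<ellipse> center (%.1f, %.1f)  a=%.1f b=%.1f  theta=%.2f rad\n",
              x$cx, x$cy, x$a, x$b, x$theta))
  invisible(x)
}

# --- full-scene segmentation ------------------------------------------------

.seed_mask_from_labels <- function(labels, ellipses = NULL, params = NULL) {
  labels <- relabel_components(labels)
  k <- max(labels, 0L)
  counts <- if (k > 0L) tabulate(labels[labels > 0L], k) else integer(0)
  centroids <- matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y")))
  if (k > 0L) {
    cx <- vapply(seq_len(k), function(i) mean(col(labels)[labels == i]), numeric(1))
    cy <- vapply(seq_len(k), function(i) mean(row(labels)[labels == i]), numeric(1))
    centroids <- cbind(x = cx, y = cy)
  }
  structure(list(labels = labels, n = k, pixel_counts = counts,
                 centroids = centroids, ellipses = ellipses, params = params),
            class = "seed_mask")
}

#' Segment a scene into per-seed masks
#'
#' Runs the full chain on the configured band slice: intensity-window
#' threshold, 8-connected component labeling, minimum-size filter, hole
#' filling, and (optionally) ellipse decomposition of components that merge
#' several touching seeds. Deterministic for fixed input and
#' \code{params$rng_seed}.
#'
#' @param cube a \code{\link{hypercube}}.
#' @param params a \code{\link{segmentation_params}}.
#' @return an object of class \code{"seed_mask"}: integer label image
#'   (\code{labels}, 0 = background, 1..K = seeds in reading order), seed
#'   count \code{n}, \code{pixel_counts}, \code{centroids} (x, y), and the
#'   fitted \code{ellipses} when ellipse fitting ran.
#' @export
segment_scene <- function(cube, params = segmentation_params()) {
  stopifnot(inherits(cube, "hypercube"), inherits(params, "segmentation_params"))
  if (params$band_id > n_bands(cube))
    stop(sprintf("band_id %d out of range 1..%d", params$band_id, n_bands(cube)))
  slice <- band_slice(cube, params$band_id)
  mask <- threshold_mask(slice, params$i_min, params$i_max)
  labels <- label_components(mask)
  labels <- filter_components(labels, params$min_pixels)
  k0 <- max(labels, 0L)
  if (k0 == 0L) {
    warning("no seeds found (blank scene or misconfigured intensity window)")
    return(.seed_mask_from_labels(labels, params = params))
  }
  out <- matrix(0L, nrow(labels), ncol(labels))
  ellipses <- list()
  nxt <- 1L
  for (i in seq_len(k0)) {
    comp <- fill_holes(labels == i)
    comp[out > 0L] <- FALSE       # never overwrite an already-assigned seed
    if (params$ellipse_fitting) {
      dec <- decompose_overlaps(comp, max_k = params$max_ellipses,
                                min_size = params$min_pixels,
                                rng_seed = params$rng_seed + i)
      for (j in seq_len(dec$k)) {
        out[dec$masks[[j]]] <- nxt
        ellipses[[nxt]] <- dec$ellipses[[j]]
        nxt <- nxt + 1L
      }
    } else {
      out[comp] <- nxt
      nxt <- nxt + 1L
    }
  }
  # decomposition sub-masks below min_pixels cannot stand as seeds
  out_f <- filter_components(out, params$min_pixels)
  ell_final <- NULL
  kf <- max(out_f, 0L)
  if (params$ellipse_fitting && kf > 0L) {
    ell_final <- vector("list", kf)
    for (j in seq_len(kf))                    # each survivor keeps its fit
      ell_final[[j]] <- ellipses[[out[out_f == j][1L]]]
  }
  .seed_mask_from_labels(out_f, ellipses = ell_final, params = params)
}

#' @export
print.seed_mask <- function(x, ...) {
  cat(sprintf("<seed_mask> %d seed(s) over a %d x %d (y, x) frame\n",
              x$n, nrow(x$labels), ncol(x$labels)))
  if (x$n > 0L)
    cat("  pixel counts:", paste(x$pixel_counts, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.seed_mask <- function(x, ...) {
  cols <- c("black", grDevices::hcl.colors(max(x$n, 1L), "Spectral"))
  graphics::image(t(x$labels)[, nrow(x$labels):1], col = cols, axes = FALSE, ...)
  invisible(x)
}
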