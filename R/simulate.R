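# Synthetic seed-tray scenes with planted ground truth: a near-dark platform,
# ellipse-shaped seeds from two treatment groups whose reflectance curves
# differ, additive sensor noise, and matching white/dark reference scans.
# Every stage of the pipeline and all classifiers are testable against the
# planted truth without any real acquisition.

#' Default control / heat-stress reflectance curves
#'
#' Constructs a smooth pair of group mean-reflectance curves in [0, 1] with
#' the qualitative structure seen in heat-stressed vs control seeds: the
#' stressed (HS) curve sits at or above the control curve everywhere, the two
#' nearly coincide in the 671--771 nm window, and the gap opens to at least
#' 0.03 reflectance units beyond 1000 nm.
#'
#' With \code{signal_range} set, the gap is instead confined to that window
#' (raised-cosine tapered, exactly zero outside) — useful for planting a
#' signal in a known spectral region when testing wavelength-importance
#' recovery.
#'
#' @param wavelengths ascending wavelength grid (nm).
#' @param gap peak reflectance gap between the groups.
#' @param signal_range optional \code{c(lo, hi)} nm window confining the gap.
#' @return list with numeric vectors \code{control} and \code{hs}.
#' @export
default_group_curves <- function(wavelengths, gap = 0.05, signal_range = NULL) {
  w <- as.numeric(wavelengths)
  if (is.unsorted(w, strictly = TRUE)) stop("wavelengths must be ascending")
  control <- 0.30 + 0.15 * exp(-((w - 1150) / 400)^2)
  if (is.null(signal_range)) {
    delta <- gap * stats::plogis((w - 885) / 40)
  } else {
    lo <- signal_range[1L]; hi <- signal_range[2L]
    taper <- min(100, (hi - lo) / 3)
    up <- pmin(1, pmax(0, (w - lo) / taper))
    down <- pmin(1, pmax(0, (hi - w) / taper))
    delta <- gap * (0.5 * (1 - cos(pi * up))) * (0.5 * (1 - cos(pi * down)))
    delta[w <= lo | w >= hi] <- 0
  }
  list(control = control, hs = control + delta)
}

#' Specification of a synthetic seed scene
#'
#' @param nx,ny frame size (samples across track, lines along scan).
#' @param n_bands spectral bands, evenly spaced over \code{wl_range}.
#' @param wl_range spectral range in nm.
#' @param n_seeds number of seeds.
#' @param a_range,b_range semi-major/minor axis ranges in pixels.
#' @param overlap_fraction target pairwise overlap as a fraction of the
#'   smaller seed's area, in [0, 0.5); 0 keeps all seeds separated. When
#'   positive, seeds are placed in touching pairs at that overlap.
#' @param groups per-seed group labels (\code{"control"}/\code{"hs"});
#'   default alternates so both groups are balanced.
#' @param curves list with \code{control} and \code{hs} reflectance vectors
#'   on the band grid; default \code{\link{default_group_curves}}.
#' @param dark_level,white_level dark/white reference intensity (counts).
#' @param background_reflectance platform reflectance (painted black).
#' @param noise_sd additive Gaussian sensor noise, counts per pixel-band.
#' @param rng_seed seed making the whole scene reproducible.
#' @return an object of class \code{"scene_spec"}.
#' @export
scene_spec <- function(nx = 200L, ny = 200L, n_bands = 60L,
                       wl_range = c(600, 1700), n_seeds = 10L,
                       a_range = c(10, 16), b_range = c(5, 9),
                       overlap_fraction = 0, groups = NULL, curves = NULL,
                       dark_level = 100, white_level = 3000,
                       background_reflectance = 0.05, noise_sd = 20,
                       rng_seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction >= 0.5)
    stop("overlap_fraction must be in [0, 0.5)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  wavelengths <- seq(wl_range[1L], wl_range[2L], length.out = n_bands)
  if (is.null(groups))
    groups <- rep(c("control", "hs"), length.out = n_seeds)
  if (length(groups) != n_seeds) stop("groups must have one entry per seed")
  if (is.null(curves)) curves <- default_group_curves(wavelengths)
  if (length(curves$control) != n_bands || length(curves$hs) != n_bands)
    stop("group curves must be defined on the full band grid")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 n_bands = as.integer(n_bands), wavelengths = wavelengths,
                 n_seeds = as.integer(n_seeds), a_range = a_range,
                 b_range = b_range, overlap_fraction = overlap_fraction,
                 groups = groups, curves = curves, dark_level = dark_level,
                 white_level = white_level,
                 background_reflectance = background_reflectance,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# rasterize an ellipse into a logical (ny x nx) matrix
.raster_ellipse <- function(nx, ny, cx, cy, a, b, theta) {
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  ys <- matrix(seq_len(ny), ny, nx) - cy
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a synthetic scene with ground truth
#'
#' Renders the scene described by a \code{\link{scene_spec}}: seeds are
#' placed with bounded retries (separated, or in pairs at the target overlap
#' fraction), pixel intensities are built as
#' \code{dark + reflectance * (white - dark)} plus independent Gaussian
#' noise, and matching white/dark reference scans are produced so that
#' \code{\link{calibrate}} recovers the planted reflectance curves in
#' expectation. Fully reproducible from \code{spec$rng_seed}.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @return list with \code{raw} (intensity \code{\link{hypercube}}),
#'   \code{refs} (a \code{\link{reference_set}}) and \code{truth} (label
#'   image, per-seed groups, planted ellipses, planted curves).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nx <- spec$nx; ny <- spec$ny; L <- spec$n_bands
  with_rng_seed(spec$rng_seed, {
    labels <- matrix(0L, ny, nx)
    ellipses <- vector("list", spec$n_seeds)
    occupied <- matrix(FALSE, ny, nx)
    pair_overlap <- spec$overlap_fraction > 0
    i <- 1L
    while (i <= spec$n_seeds) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        a <- stats::runif(1, spec$a_range[1L], spec$a_range[2L])
        b <- stats::runif(1, spec$b_range[1L], spec$b_range[2L])
        th <- stats::runif(1, 0, pi)
        attach_to <- if (pair_overlap && i %% 2L == 0L) ellipses[[i - 1L]] else NULL
        if (is.null(attach_to)) {
          cx <- stats::runif(1, a + 2, nx - a - 2)
          cy <- stats::runif(1, a + 2, ny - a - 2)
          m <- .raster_ellipse(nx, ny, cx, cy, a, b, th)
          grown <- EBImage::dilate(m * 1, EBImage::makeBrush(5, "disc")) > 0
          if (!any(grown & occupied)) {
            labels[m & labels == 0L] <- i
            occupied <- occupied | m
            ellipses[[i]] <- list(cx = cx, cy = cy, a = a, b = b, theta = th)
            placed <- TRUE
            break
          }
        } else {
          # place at a center distance tuned so the rasterized intersection is
          # ~ overlap_fraction of the smaller area (binary search, monotone)
          dir <- stats::runif(1, 0, 2 * pi)
          prev <- attach_to
          mprev <- .raster_ellipse(nx, ny, prev$cx, prev$cy,
                                   prev$a, prev$b, prev$theta)
          lo_d <- 0; hi_d <- prev$a + a + 2
          ratio_at <- function(d) {
            cx <- prev$cx + d * cos(dir); cy <- prev$cy + d * sin(dir)
            m <- .raster_ellipse(nx, ny, cx, cy, a, b, th)
            sum(m & mprev) / min(sum(m), sum(mprev))
          }
          for (it in seq_len(18L)) {
            mid <- (lo_d + hi_d) / 2
            if (ratio_at(mid) > spec$overlap_fraction) lo_d <- mid else hi_d <- mid
          }
          d <- hi_d
          cx <- prev$cx + d * cos(dir); cy <- prev$cy + d * sin(dir)
          if (cx < a + 2 || cx > nx - a - 2 || cy < a + 2 || cy > ny - a - 2) next
          m <- .raster_ellipse(nx, ny, cx, cy, a, b, th)
          r <- sum(m & mprev) / min(sum(m), sum(mprev))
          # must touch its partner but nothing else
          others <- occupied & !mprev
          grown <- EBImage::dilate(m * 1, EBImage::makeBrush(5, "disc")) > 0
          if (r <= spec$overlap_fraction && r > 0 && !any(grown & others)) {
            labels[m & labels == 0L] <- i   # earlier seed keeps the overlap
            occupied <- occupied | m
            ellipses[[i]] <- list(cx = cx, cy = cy, a = a, b = b, theta = th)
            placed <- TRUE
            break
          }
        }
      }
      if (!placed)
        stop("could not place seed ", i, " within overlap constraints")
      i <- i + 1L
    }

    # reflectance per pixel: background, or the owning seed's group curve
    curve_mat <- rbind(rep(spec$background_reflectance, L),
                       spec$curves$control, spec$curves$hs)
    row_idx <- ifelse(labels == 0L, 1L,
                      ifelse(matrix(spec$groups[pmax(labels, 1L)] == "hs",
                                    ny, nx), 3L, 2L))
    refl <- array(curve_mat[as.vector(row_idx), ], dim = c(ny, nx, L))
    io <- spec$dark_level + refl * (spec$white_level - spec$dark_level) +
      stats::rnorm(length(refl), sd = spec$noise_sd)
    raw <- hypercube(io, wavelengths = spec$wavelengths, dtype_code = 4L)

    # references are full scans of the white tile / capped lens, matching the
    # sample frame height
    ny_ref <- ny
    white <- hypercube(array(spec$white_level +
                               stats::rnorm(ny_ref * nx * L, sd = spec$noise_sd),
                             dim = c(ny_ref, nx, L)),
                       wavelengths = spec$wavelengths, dtype_code = 4L)
    dark <- hypercube(array(spec$dark_level +
                              stats::rnorm(ny_ref * nx * L, sd = spec$noise_sd),
                            dim = c(ny_ref, nx, L)),
                      wavelengths = spec$wavelengths, dtype_code = 4L)

    truth <- structure(list(labels = labels, groups = spec$groups,
                            ellipses = ellipses, curves = spec$curves,
                            wavelengths = spec$wavelengths),
                       class = "scene_truth")
    list(raw = raw, refs = reference_set(white, dark), truth = truth)
  })
}

#' Match recovered seeds to planted ground truth
#'
#' Pairs each recovered seed with the nearest planted ellipse center and
#' reports the planted group, the matched planted index and the center error
#' (recovered ellipse center where available, else the mask centroid).
#'
#' @param masks a \code{seed_mask} from \code{\link{segment_scene}}.
#' @param truth the \code{truth} element of \code{\link{generate_scene}}.
#' @return data frame: \code{seed}, \code{planted}, \code{group},
#'   \code{center_error_px}.
#' @export
match_truth <- function(masks, truth) {
  if (masks$n == 0L)
    return(data.frame(seed = integer(), planted = integer(),
                      group = character(), center_error_px = numeric()))
  tc <- cbind(vapply(truth$ellipses, `[[`, numeric(1), "cx"),
              vapply(truth$ellipses, `[[`, numeric(1), "cy"))
  rc <- if (!is.null(masks$ellipses))
    cbind(vapply(masks$ellipses, `[[`, numeric(1), "cx"),
          vapply(masks$ellipses, `[[`, numeric(1), "cy"))
  else masks$centroids
  planted <- apply(rc, 1L, function(p)
    which.min((tc[, 1L] - p[1L])^2 + (tc[, 2L] - p[2L])^2))
  err <- sqrt(rowSums((rc - tc[planted, , drop = FALSE])^2))
  data.frame(seed = seq_len(masks$n), planted = planted,
             group = truth$groups[planted], center_error_px = err)
}
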