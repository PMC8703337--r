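# Reflectance calibration against white/dark references and trimming of the
# noisy spectral extremes.

#' Bundle white and dark reference cubes
#'
#' The white reference is a scan of a near-100%-reflectance standard tile; the
#' dark reference is captured with the lens capped. Both must share the sample
#' cube's band count. References are validated to satisfy mean(white) >
#' mean(dark) band-wise; failing that they were almost certainly swapped.
#'
#' @param white,dark \code{\link{hypercube}}s (full reference scans).
#' @return an object of class \code{"reference_set"}.
#' @export
reference_set <- function(white, dark) {
  stopifnot(inherits(white, "hypercube"), inherits(dark, "hypercube"))
  if (n_bands(white) != n_bands(dark))
    stop("white and dark references have different band counts")
  wm <- apply(white$data, 3L, mean)
  dm <- apply(dark$data, 3L, mean)
  if (any(wm <= dm))
    stop("mean(white) <= mean(dark) for ", sum(wm <= dm),
         " band(s): references swapped or invalid")
  structure(list(white = white, dark = dark), class = "reference_set")
}

# Reduce a reference cube to one scan line per band (x by band matrix) by
# averaging over the scan direction y. Standard line-scan practice: the
# reference tile fills the across-track line and repeats down the scan.
.reference_profile <- function(ref) {
  d <- dim(ref$data)
  if (d[1L] == 1L) return(ref$data[1L, , , drop = TRUE])
  apply(ref$data, c(2L, 3L), mean)
}

#' Calibrate raw intensity to reflectance
#'
#' Applies the standard two-point reflectance calibration
#' \deqn{I_c = (I_o - I_d) / (I_w - I_d)}
#' elementwise, where \eqn{I_o} is the raw sample cube and \eqn{I_w},
#' \eqn{I_d} the white and dark references. References may be full cubes of
#' any scan length: each is averaged over its scan direction to one profile
#' per (sample, band) cell and broadcast down the sample cube's y axis.
#'
#' Where the reference contrast \eqn{|I_w - I_d|} falls below \code{eps}
#' (dead or saturated sensor cells) the output is set to 0 and the affected
#' pixel count is reported via a message, so isolated dead pixels cannot
#' poison seed means. Reflectance is deliberately not clipped to [0, 1]:
#' specular pixels can legitimately exceed the white tile.
#'
#' @param raw a \code{\link{hypercube}} of raw intensity (\eqn{I_o}).
#' @param refs a \code{\link{reference_set}}.
#' @param eps contrast threshold below which a cell is treated as degenerate.
#' @return a \code{\link{hypercube}} flagged as reflectance.
#' @export
calibrate <- function(raw, refs, eps = 1e-6) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_set"))
  if (n_bands(refs$white) != n_bands(raw))
    stop(sprintf("band-count mismatch: raw has %d bands, references %d",
                 n_bands(raw), n_bands(refs$white)))
  d <- dim(raw$data)
  wp <- .reference_profile(refs$white)   # x by band
  dp <- .reference_profile(refs$dark)
  if (!all(dim(wp) == c(d[2L], d[3L])))
    stop(sprintf("reference x-extent/bands (%d x %d) incompatible with raw (%d x %d)",
                 dim(wp)[1L], dim(wp)[2L], d[2L], d[3L]))
  denom <- wp - dp
  dead <- abs(denom) < eps
  if (any(dead)) {
    message(sum(dead), " reference cell(s) with |white - dark| < eps; output 0 there")
    denom[dead] <- 1
  }
  # broadcast x-by-band profiles across y (y is the first axis)
  ny <- d[1L]
  dark_full  <- aperm(array(dp,    dim = c(d[2L], d[3L], ny)), c(3L, 1L, 2L))
  denom_full <- aperm(array(denom, dim = c(d[2L], d[3L], ny)), c(3L, 1L, 2L))
  ic <- (raw$data - dark_full) / denom_full
  if (any(dead)) {
    dead_full <- aperm(array(dead, dim = c(d[2L], d[3L], ny)), c(3L, 1L, 2L))
    ic[dead_full] <- 0
  }
  hypercube(ic, wavelengths = if (raw$wavelengths_synthetic) NULL else raw$wavelengths,
            interleave = raw$interleave, dtype_code = 4L,
            source_path = raw$source_path, reflectance = TRUE)
}

#' Trim noisy bands at the spectral extremes
#'
#' Line-scan sensors are noisy at the edges of their spectral range, so the
#' first and last bands are routinely dropped before analysis. The normative
#' rule is a wavelength window: bands whose center wavelength \eqn{w}
#' satisfies \code{lo_nm <= w <= hi_nm} are retained (default 655–1642 nm).
#' An alternative fraction-based mode removes \code{ceiling(fraction * L)}
#' bands from each end.
#'
#' @param cube a \code{\link{hypercube}} with parsed (non-synthetic)
#'   wavelengths for window mode.
#' @param lo_nm,hi_nm window bounds in nm, inclusive.
#' @param mode \code{"window"} (default) or \code{"fraction"}.
#' @param fraction per-end trim fraction for \code{mode = "fraction"}.
#' @return list with elements \code{cube} (the trimmed hypercube) and
#'   \code{window} (class \code{"band_window"}: \code{lo_nm}, \code{hi_nm},
#'   \code{retained_indices}, 1-based and contiguous).
#' @export
#' @examples
#' wl <- seq(600, 1700, length.out = 268)
#' cube <- hypercube(array(1, c(2, 2, 268)), wavelengths = wl)
#' tr <- trim_bands(cube, 655, 1642)
#' length(tr$window$retained_indices)  # 239
trim_bands <- function(cube, lo_nm = 655, hi_nm = 1642,
                       mode = c("window", "fraction"), fraction = 0.05) {
  stopifnot(inherits(cube, "hypercube"))
  mode <- match.arg(mode)
  L <- n_bands(cube)
  if (mode == "fraction") {
    k <- ceiling(fraction * L)
    if (2L * k >= L) stop("fraction trim removes all bands")
    keep <- seq.int(k + 1L, L - k)
  } else {
    if (cube$wavelengths_synthetic)
      stop("window trim needs parsed wavelengths; header had none")
    if (lo_nm >= hi_nm) stop("lo_nm must be < hi_nm")
    keep <- which(cube$wavelengths >= lo_nm & cube$wavelengths <= hi_nm)
    if (length(keep) == 0L)
      stop(sprintf("window [%g, %g] nm retains no bands (range %g..%g)",
                   lo_nm, hi_nm, min(cube$wavelengths), max(cube$wavelengths)))
  }
  out <- hypercube(cube$data[, , keep, drop = FALSE],
                   wavelengths = cube$wavelengths[keep],
                   interleave = cube$interleave, dtype_code = cube$dtype_code,
                   source_path = cube$source_path, reflectance = cube$reflectance)
  window <- structure(
    list(lo_nm = min(out$wavelengths), hi_nm = max(out$wavelengths),
         retained_indices = keep),
    class = "band_window")
  list(cube = out, window = window)
}
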