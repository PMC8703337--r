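#' Hypercube: a hyperspectral image cube
#'
#' In-memory container for a line-scan hyperspectral image. The data array is
#' always stored in \code{(line y, sample x, band)} order, whatever the on-disk
#' interleave was; every other function in the package relies on this axis
#' convention. The y axis grows with scan duration, x is the across-track
#' sensor line, and the band axis carries one slice per wavelength.
#'
#' @param data numeric 3-D array indexed \code{[y, x, band]}.
#' @param wavelengths numeric vector of band-center wavelengths in nm, strictly
#'   increasing, one per band. If \code{NULL}, a synthetic index \code{1..L} is
#'   used and the cube is flagged via \code{wavelengths_synthetic}.
#' @param interleave on-disk interleave this cube was read from or should be
#'   written with: \code{"bil"}, \code{"bip"} or \code{"bsq"}.
#' @param dtype_code ENVI data-type tag (1 byte, 2 int16, 3 int32, 4 float32,
#'   5 float64, 12 uint16).
#' @param source_path path of the header this cube was read from, or \code{NA}.
#' @param reflectance logical; \code{TRUE} once the cube has been calibrated to
#'   reflectance, \code{FALSE} for raw intensity.
#'
#' @return An object of class \code{"hypercube"}: a list with elements
#'   \code{data}, \code{wavelengths}, \code{wavelengths_synthetic},
#'   \code{interleave}, \code{dtype_code}, \code{source_path},
#'   \code{reflectance}.
#' @export
#' @examples
#' cube <- hypercube(array(runif(4 * 5 * 3), c(4, 5, 3)),
#'                   wavelengths = c(600, 650, 700))
#' dim(cube)
#' n_bands(cube)
hypercube <- function(data, wavelengths = NULL, interleave = "bil",
                      dtype_code = 4L, source_path = NA_character_,
                      reflectance = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array indexed (y, x, band)")
  if (any(dim(data) < 1L))
    stop("all hypercube dimensions must be >= 1")
  L <- dim(data)[3L]
  synthetic <- is.null(wavelengths)
  if (synthetic) wavelengths <- as.numeric(seq_len(L))
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != L)
    stop(sprintf("wavelength vector length (%d) != band count (%d)",
                 length(wavelengths), L))
  if (L > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  interleave <- match.arg(tolower(interleave), c("bil", "bip", "bsq"))
  if (!dtype_code %in% c(1L, 2L, 3L, 4L, 5L, 12L))
    stop("unsupported ENVI data type code: ", dtype_code)
  structure(
    list(data = data,
         wavelengths = wavelengths,
         wavelengths_synthetic = synthetic,
         interleave = interleave,
         dtype_code = as.integer(dtype_code),
         source_path = source_path,
         reflectance = isTRUE(reflectance)),
    class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Number of spectral bands in a hypercube
#' @param x a \code{hypercube}.
#' @return integer band count.
#' @export
n_bands <- function(x) dim(x$data)[3L]

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines (y) x %d samples (x) x %d bands\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  wavelengths: %.2f .. %.2f nm%s\n",
              min(x$wavelengths), max(x$wavelengths),
              if (x$wavelengths_synthetic) " (synthetic band index)" else ""))
  cat(sprintf("  interleave: %s  dtype: %d  %s\n", x$interleave, x$dtype_code,
              if (x$reflectance) "reflectance" else "intensity"))
  if (!is.na(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' Extract one band as a 2-D image slice
#'
#' @param cube a \code{hypercube}.
#' @param band_id 1-based band index, as printed in headers and configs.
#' @return numeric matrix \code{[y, x]}.
#' @export
band_slice <- function(cube, band_id) {
  stopifnot(inherits(cube, "hypercube"))
  band_id <- as.integer(band_id)
  if (band_id < 1L || band_id > n_bands(cube))
    stop(sprintf("band_id %d out of range 1..%d", band_id, n_bands(cube)))
  cube$data[, , band_id]
}
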