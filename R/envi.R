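# ENVI header/raw pair I/O. The ENVI "format" is an ASCII header (.hdr) with
# samples/lines/bands/interleave/data type/byte order/wavelength fields next
# to a headerless binary file; no installed package reads it, so the parser
# and binary plumbing live here.

# ENVI data type tag -> readBin/writeBin arguments
.envi_dtypes <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE, integer = TRUE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE,  integer = TRUE),
  `3`  = list(what = "integer", size = 4L, signed = TRUE,  integer = TRUE),
  `4`  = list(what = "double",  size = 4L, signed = TRUE,  integer = FALSE),
  `5`  = list(what = "double",  size = 8L, signed = TRUE,  integer = FALSE),
  `12` = list(what = "integer", size = 2L, signed = FALSE, integer = TRUE))

# Extensions tried, in order, when locating the binary companion of a header.
.envi_data_exts <- c("", ".raw", ".img", ".dat")

#' Parse an ENVI ASCII header
#'
#' Reads \code{key = value} fields; values wrapped in braces (such as the
#' wavelength list) may span multiple lines. Keys are lower-cased.
#'
#' @param header_path path to a \code{.hdr} file.
#' @return named list of character values (brace lists split on commas).
#' @keywords internal
parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  fields <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (!grepl("=", ln, fixed = TRUE)) { i <- i + 1L; next }
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{")) {
      while (!grepl("}", val, fixed = TRUE) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[[i]]))
      }
      val <- gsub("[{}]", "", val)
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      val <- val[nzchar(val)]
    }
    fields[[key]] <- val
    i <- i + 1L
  }
  fields
}

.find_envi_data <- function(header_path) {
  stem <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  for (ext in .envi_data_exts) {
    cand <- paste0(stem, ext)
    if (file.exists(cand) && !identical(normalizePath(cand, mustWork = FALSE),
                                        normalizePath(header_path, mustWork = FALSE)))
      return(cand)
  }
  NULL
}

#' Read an ENVI hypercube
#'
#' Reads a header/raw pair and returns the cube with the data re-ordered to
#' the package's internal \code{(y, x, band)} axis order regardless of the
#' on-disk interleave. The binary companion is located by trying, in order,
#' the header's stem with no extension, then \code{.raw}, \code{.img},
#' \code{.dat}. If the header carries no wavelength list a synthetic band
#' index \code{1..L} is substituted and flagged on the returned cube.
#'
#' @param header_path path to the \code{.hdr} file.
#' @return a \code{\link{hypercube}}.
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  h <- parse_envi_header(header_path)
  for (f in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(h[[f]])) stop("header field missing: '", f, "' in ", header_path)
  nx <- as.integer(h[["samples"]]); ny <- as.integer(h[["lines"]])
  nl <- as.integer(h[["bands"]])
  dtype <- as.integer(h[["data type"]])
  spec <- .envi_dtypes[[as.character(dtype)]]
  if (is.null(spec)) stop("unsupported ENVI data type: ", dtype)
  interleave <- tolower(h[["interleave"]])
  if (!interleave %in% c("bil", "bip", "bsq"))
    stop("unsupported interleave: '", interleave, "'")
  endian <- if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) == 1L)
    "big" else "little"
  offset <- if (!is.null(h[["header offset"]])) as.integer(h[["header offset"]]) else 0L

  data_path <- .find_envi_data(header_path)
  if (is.null(data_path))
    stop("no data file found for header ", header_path,
         " (tried extensions: ", paste(shQuote(.envi_data_exts), collapse = ", "), ")")
  n_values <- as.double(nx) * ny * nl
  expected_bytes <- offset + n_values * spec$size
  actual_bytes <- file.size(data_path)
  if (actual_bytes < expected_bytes)
    stop(sprintf(paste0("header/data size mismatch for %s: samples*lines*bands = ",
                        "%d*%d*%d requires %.0f bytes, data file has %.0f"),
                 data_path, nx, ny, nl, expected_bytes, actual_bytes))

  con <- file(data_path, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", n = offset)
  vals <- readBin(con, what = spec$what, n = n_values, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n_values)
    stop("short read from ", data_path)
  # On-disk fastest-to-slowest axis order:
  #   bsq: x, y, band;  bil: x, band, y;  bip: band, x, y
  arr <- switch(interleave,
    bsq = aperm(array(vals, dim = c(nx, ny, nl)), c(2L, 1L, 3L)),
    bil = aperm(array(vals, dim = c(nx, nl, ny)), c(3L, 1L, 2L)),
    bip = aperm(array(vals, dim = c(nl, nx, ny)), c(3L, 2L, 1L)))

  wl <- NULL
  if (!is.null(h[["wavelength"]])) {
    wl <- suppressWarnings(as.numeric(h[["wavelength"]]))
    if (anyNA(wl) || length(wl) != nl) {
      warning("unparseable wavelength list in ", header_path,
              "; using synthetic band index")
      wl <- NULL
    }
  }
  hypercube(arr, wavelengths = wl, interleave = interleave,
            dtype_code = dtype, source_path = header_path)
}

#' Write a hypercube as an ENVI header/raw pair
#'
#' The data file shares the header's stem with a \code{.raw} extension and is
#' written in the cube's interleave, little-endian. Integer data types
#' round-trip bit exactly through \code{\link{read_envi}}; float32
#' (\code{dtype_code = 4}) round-trips within single-precision representation.
#'
#' @param cube a \code{\link{hypercube}}.
#' @param header_path destination \code{.hdr} path.
#' @return invisibly, the data-file path.
#' @export
write_envi <- function(cube, header_path) {
  stopifnot(inherits(cube, "hypercube"))
  spec <- .envi_dtypes[[as.character(cube$dtype_code)]]
  d <- dim(cube$data)
  ny <- d[1L]; nx <- d[2L]; nl <- d[3L]
  data_path <- paste0(sub("\\.hdr$", "", header_path, ignore.case = TRUE), ".raw")

  hdr <- c(
    "ENVI",
    sprintf("samples = %d", nx),
    sprintf("lines = %d", ny),
    sprintf("bands = %d", nl),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", cube$dtype_code),
    sprintf("interleave = %s", cube$interleave),
    "byte order = 0")
  if (!cube$wavelengths_synthetic) {
    hdr <- c(hdr, "wavelength units = nm",
             paste0("wavelength = { ",
                    paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                          collapse = ", "), " }"))
  }
  ok <- tryCatch({ writeLines(hdr, header_path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write header: ", header_path)

  # internal (y, x, band) -> on-disk fastest-to-slowest axis order
  arr <- switch(cube$interleave,
    bsq = aperm(cube$data, c(2L, 1L, 3L)),
    bil = aperm(cube$data, c(2L, 3L, 1L)),
    bip = aperm(cube$data, c(3L, 2L, 1L)))
  vals <- as.vector(arr)
  vals <- if (spec$integer) as.integer(round(vals)) else as.double(vals)
  con <- file(data_path, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = spec$size, endian = "little")
  invisible(data_path)
}

#' Resolve a batch-input pattern to header/data pairs
#'
#' Expands a filename glob (for example \code{"scans/*.hdr"}) into an ordered
#' manifest of header/data pairs. Ordering is deterministic lexicographic.
#' Headers whose binary companion cannot be located are reported with a
#' warning rather than silently dropped; a pattern matching nothing yields an
#' empty manifest with a warning, not an error.
#'
#' @param pattern filename glob for header files.
#' @return data frame of class \code{"batch_manifest"} with columns
#'   \code{header_path}, \code{data_path}.
#' @export
resolve_batch <- function(pattern) {
  headers <- sort(unique(Sys.glob(pattern)), method = "radix")
  entries <- data.frame(header_path = character(), data_path = character(),
                        stringsAsFactors = FALSE)
  orphans <- character()
  for (hp in headers) {
    dp <- .find_envi_data(hp)
    if (is.null(dp)) orphans <- c(orphans, hp)
    else entries <- rbind(entries, data.frame(header_path = hp, data_path = dp,
                                              stringsAsFactors = FALSE))
  }
  if (length(orphans))
    warning("headers without a data file (skipped): ",
            paste(orphans, collapse = ", "))
  if (length(headers) == 0L)
    warning("pattern matched no header files: ", pattern)
  class(entries) <- c("batch_manifest", class(entries))
  entries
}
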