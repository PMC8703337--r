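# Apply seed masks across the band axis: per-seed cropped hypercubes and
# per-seed mean spectra, written as ENVI pairs and CSV.

#' Extract one cropped hypercube per seed
#'
#' Each seed's cube is cropped to its bounding box with non-seed pixels set
#' to 0 and the full band axis intact, so the output count always matches the
#' seed count.
#'
#' @param cube a \code{\link{hypercube}}.
#' @param masks a \code{seed_mask} sharing the cube's x-y shape.
#' @return list of \code{\link{hypercube}}s, one per seed, in seed order.
#' @export
extract_seed_cubes <- function(cube, masks) {
  stopifnot(inherits(cube, "hypercube"), inherits(masks, "seed_mask"))
  d <- dim(cube$data)
  if (!all(dim(masks$labels) == d[1:2]))
    stop(sprintf("mask shape (%d x %d) != cube x-y shape (%d x %d)",
                 nrow(masks$labels), ncol(masks$labels), d[1L], d[2L]))
  lapply(seq_len(masks$n), function(i) {
    sel <- masks$labels == i
    rows <- range(row(sel)[sel]); cols <- range(col(sel)[sel])
    sub <- cube$data[rows[1L]:rows[2L], cols[1L]:cols[2L], , drop = FALSE]
    submask <- sel[rows[1L]:rows[2L], cols[1L]:cols[2L]]
    sub <- sub * as.numeric(rep(submask, d[3L]))
    hypercube(array(sub, dim = c(diff(rows) + 1L, diff(cols) + 1L, d[3L])),
              wavelengths = if (cube$wavelengths_synthetic) NULL else cube$wavelengths,
              interleave = cube$interleave, dtype_code = cube$dtype_code,
              source_path = cube$source_path, reflectance = cube$reflectance)
  })
}

#' Per-seed mean spectra
#'
#' Averages each seed's pixel spectra band-wise, producing one record per
#' seed with its provenance (pixel count, centroid).
#'
#' @param cube a \code{\link{hypercube}}.
#' @param masks a \code{seed_mask} sharing the cube's x-y shape.
#' @param image_id identifier recorded with every record (defaults to the
#'   cube's source file stem).
#' @return object of class \code{"seed_spectra"}: list with \code{meta}
#'   (data frame: image_id, seed_index, pixel_count, centroid_x, centroid_y),
#'   \code{spectra} (seeds x bands matrix) and \code{wavelengths}.
#' @export
mean_spectra <- function(cube, masks, image_id = NULL) {
  stopifnot(inherits(cube, "hypercube"), inherits(masks, "seed_mask"))
  d <- dim(cube$data)
  if (!all(dim(masks$labels) == d[1:2]))
    stop("mask shape does not match cube x-y shape")
  if (is.null(image_id))
    image_id <- if (is.na(cube$source_path)) "image"
                else tools::file_path_sans_ext(basename(cube$source_path))
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])
  lab <- as.vector(masks$labels)
  spectra <- matrix(NA_real_, masks$n, d[3L])
  for (i in seq_len(masks$n))
    spectra[i, ] <- colMeans(flat[lab == i, , drop = FALSE])
  meta <- data.frame(
    image_id = rep(image_id, masks$n),
    seed_index = seq_len(masks$n),
    pixel_count = as.integer(masks$pixel_counts),
    centroid_x = if (masks$n) masks$centroids[, "x"] else numeric(0),
    centroid_y = if (masks$n) masks$centroids[, "y"] else numeric(0),
    stringsAsFactors = FALSE)
  structure(list(meta = meta, spectra = spectra,
                 wavelengths = cube$wavelengths),
            class = "seed_spectra")
}

#' @export
print.seed_spectra <- function(x, ...) {
  cat(sprintf("<seed_spectra> %d seed(s), %d band(s) (%.2f..%.2f nm)\n",
              nrow(x$meta), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
plot.seed_spectra <- function(x, col = NULL, ...) {
  if (nrow(x$spectra) == 0L) stop("no seeds to plot")
  if (is.null(col)) col <- grDevices::hcl.colors(nrow(x$spectra), "Dark 2")
  graphics::matplot(x$wavelengths, t(x$spectra), type = "l", lty = 1,
                    col = col, xlab = "wavelength (nm)",
                    ylab = "mean reflectance", ...)
  invisible(x)
}

#' Write per-seed spectra (CSV) and per-seed hypercubes (ENVI)
#'
#' Writes one CSV per image under \code{out_dir} with columns
#' \code{image_id, seed_index, pixel_count, centroid_x, centroid_y} followed
#' by one reflectance column per wavelength (named by nm to 2 decimals,
#' values at 8 significant digits), plus per-seed ENVI pairs under
#' \code{out_dir/<image_id>_seeds/}. Existing files are skipped with a log
#' line unless \code{overwrite} is set.
#'
#' @param spectra a \code{seed_spectra}.
#' @param seed_cubes optional list from \code{\link{extract_seed_cubes}}.
#' @param out_dir output directory, created if needed.
#' @param overwrite replace existing files?
#' @return invisibly, a data frame manifest (path, status).
#' @export
write_outputs <- function(spectra, seed_cubes = NULL, out_dir,
                          overwrite = FALSE) {
  stopifnot(inherits(spectra, "seed_spectra"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  image_id <- if (nrow(spectra$meta)) spectra$meta$image_id[1L] else "image"
  manifest <- data.frame(path = character(), status = character(),
                         stringsAsFactors = FALSE)
  add <- function(path, status)
    manifest <<- rbind(manifest, data.frame(path = path, status = status,
                                            stringsAsFactors = FALSE))

  csv_path <- file.path(out_dir, paste0(image_id, "_spectra.csv"))
  if (file.exists(csv_path) && !overwrite) {
    .log_line("skip (exists): ", csv_path)
    add(csv_path, "skipped")
  } else {
    df <- spectra$meta
    sp <- matrix(formatC(spectra$spectra, digits = 8L, format = "g"),
                 nrow = nrow(spectra$meta), ncol = length(spectra$wavelengths))
    colnames(sp) <- sprintf("%.2f", spectra$wavelengths)
    utils::write.csv(cbind(df, as.data.frame(sp, stringsAsFactors = FALSE)),
                     csv_path, row.names = FALSE, quote = FALSE)
    add(csv_path, "written")
  }

  if (!is.null(seed_cubes)) {
    sub <- file.path(out_dir, paste0(image_id, "_seeds"))
    dir.create(sub, showWarnings = FALSE)
    for (i in seq_along(seed_cubes)) {
      hp <- file.path(sub, sprintf("%s_seed%03d.hdr", image_id, i))
      if (file.exists(hp) && !overwrite) {
        .log_line("skip (exists): ", hp)
        add(hp, "skipped")
      } else {
        write_envi(seed_cubes[[i]], hp)
        add(hp, "written")
      }
    }
  }
  invisible(manifest)
}

#' Read a per-seed spectra CSV back
#'
#' Inverse of the CSV side of \code{\link{write_outputs}}.
#'
#' @param csv_path path written by \code{\link{write_outputs}}.
#' @return a \code{seed_spectra}.
#' @export
read_spectra_csv <- function(csv_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("image_id", "seed_index", "pixel_count",
                 "centroid_x", "centroid_y")
  wl <- as.numeric(setdiff(names(df), meta_cols))
  structure(list(meta = df[meta_cols],
                 spectra = as.matrix(df[setdiff(names(df), meta_cols)]),
                 wavelengths = wl),
            class = "seed_spectra")
}
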