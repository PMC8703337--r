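# Batch entry point: read -> (calibrate) -> (trim) -> segment -> extract ->
# write, per manifest entry, with per-image logging and failure isolation.

#' Build and validate a batch run configuration
#'
#' Collects the path, mode, calibration, trimming and segmentation settings
#' of a batch run. In reflectance mode the white and dark reference paths are
#' mandatory and checked up front (pre-flight), before any image is touched;
#' intensity mode needs no references and emits raw intensity.
#'
#' @param input_pattern glob for input header files (e.g. \code{"in/*.hdr"}).
#' @param output_dir destination directory.
#' @param mode \code{"intensity"} or \code{"reflectance"}.
#' @param white_path,dark_path reference header paths (reflectance mode).
#' @param trim \code{"window"}, \code{"fraction"} or \code{"off"}.
#' @param trim_lo_nm,trim_hi_nm wavelength window for \code{trim = "window"}.
#' @param trim_fraction per-end fraction for \code{trim = "fraction"}.
#' @param seg a \code{\link{segmentation_params}}.
#' @param write_seed_cubes write per-seed ENVI cubes as well as CSV?
#' @param overwrite overwrite existing outputs?
#' @param rng_seed seed forwarded to seeded stages.
#' @return object of class \code{"run_config"}.
#' @export
run_config <- function(input_pattern, output_dir,
                       mode = c("intensity", "reflectance"),
                       white_path = NULL, dark_path = NULL,
                       trim = c("window", "fraction", "off"),
                       trim_lo_nm = 655, trim_hi_nm = 1642,
                       trim_fraction = 0.05,
                       seg = segmentation_params(),
                       write_seed_cubes = TRUE, overwrite = FALSE,
                       rng_seed = 1L) {
  mode <- match.arg(mode)
  trim <- match.arg(trim)
  if (mode == "reflectance" && (is.null(white_path) || is.null(dark_path)))
    stop("reflectance mode requires white_path and dark_path")
  structure(list(input_pattern = input_pattern, output_dir = output_dir,
                 mode = mode, white_path = white_path, dark_path = dark_path,
                 trim = trim, trim_lo_nm = trim_lo_nm,
                 trim_hi_nm = trim_hi_nm, trim_fraction = trim_fraction,
                 seg = seg, write_seed_cubes = isTRUE(write_seed_cubes),
                 overwrite = isTRUE(overwrite),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML form round-trips losslessly through \code{\link{run_config}}.
#'
#' @param path YAML file path.
#' @return \code{read_run_config}: a \code{run_config};
#'   \code{write_run_config}: the path, invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(segmentation_params, y$seg)
  y$seg <- NULL
  do.call(run_config, c(y, list(seg = seg)))
}

#' @rdname read_run_config
#' @param config a \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$seg <- unclass(y$seg)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Process one hypercube through the pipeline
#'
#' @param header_path input header.
#' @param config a \code{\link{run_config}}.
#' @param refs pre-loaded \code{\link{reference_set}} or \code{NULL}.
#' @return list with \code{masks}, \code{spectra}, \code{manifest}.
#' @keywords internal
process_image <- function(header_path, config, refs = NULL) {
  cube <- read_envi(header_path)
  # masks come from the raw intensity slice (the intensity window is on the
  # camera's count scale); calibration and trimming apply to the spectra
  masks <- segment_scene(cube, config$seg)
  if (config$mode == "reflectance")
    cube <- calibrate(cube, refs)
  if (config$trim == "window" && !cube$wavelengths_synthetic) {
    cube <- trim_bands(cube, config$trim_lo_nm, config$trim_hi_nm)$cube
  } else if (config$trim == "fraction") {
    cube <- trim_bands(cube, mode = "fraction",
                       fraction = config$trim_fraction)$cube
  }
  spectra <- mean_spectra(cube, masks)
  cubes <- if (config$write_seed_cubes) extract_seed_cubes(cube, masks) else NULL
  manifest <- write_outputs(spectra, cubes, config$output_dir,
                            overwrite = config$overwrite)
  list(masks = masks, spectra = spectra, manifest = manifest)
}

#' Run a batch of hypercubes through the pipeline
#'
#' Resolves the input pattern, pre-loads references in reflectance mode, and
#' processes every image: read, calibrate (reflectance mode), trim bands,
#' segment, extract, write. A failing image is logged and isolated — the
#' batch continues — and the summary manifest is always written to
#' \code{output_dir/run_manifest.json}.
#'
#' @param config a \code{\link{run_config}}.
#' @return (invisibly) list with \code{status} (0 if every image succeeded,
#'   1 otherwise) and \code{images} (per-image data frame: path, seed count,
#'   ok flag, message).
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  refs <- NULL
  if (config$mode == "reflectance") {
    refs <- reference_set(read_envi(config$white_path),
                          read_envi(config$dark_path))
  }
  entries <- resolve_batch(config$input_pattern)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(entries)
  .log_line(sprintf("batch: %d image(s), mode=%s", n, config$mode))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    hp <- entries$header_path[i]
    .log_line(sprintf("processing image %d/%d: %s", i, n, hp))
    res <- tryCatch({
      r <- process_image(hp, config, refs)
      .log_line(sprintf("  %d seed(s) extracted", r$masks$n))
      data.frame(header_path = hp, n_seeds = r$masks$n, ok = TRUE,
                 message = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      .log_line("  FAILED: ", conditionMessage(e))
      data.frame(header_path = hp, n_seeds = NA_integer_, ok = FALSE,
                 message = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  images <- if (n) do.call(rbind, rows)
            else data.frame(header_path = character(), n_seeds = integer(),
                            ok = logical(), message = character())
  status <- if (n > 0L && !all(images$ok)) 1L else 0L
  jsonlite::write_json(list(status = status, images = images),
                       file.path(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(status = status, images = images))
}
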