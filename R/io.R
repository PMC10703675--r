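#' @title File formats
#' @description
#' Stacks and maps travel as multi-page 32-bit float TIFF. TIFF float
#' storage here is normalized to the unit range; the physical scale
#' factor and the timing metadata live in a sidecar JSON next to the TIFF
#' (`<file>.json`), which avoids TIFF-tag dialect ambiguity. Time series
#' use `time_s,fluorescence` CSV and spectra `wavelength_nm,value` CSV.
#' @name actinometry-io
NULL

.sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack to TIFF with a JSON sidecar
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @param force Overwrite existing outputs (default FALSE -> error).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, force = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  if (!force && (file.exists(path) || file.exists(.sidecar_path(path))))
    stop(sprintf("'%s' exists; use force = TRUE to overwrite", path))
  frames <- stack$frames
  # affine map onto [0, 1]: TIFF samples are stored unsigned, and noisy
  # frames can dip below zero; offset and scale travel in the sidecar
  offset <- min(frames)
  scale <- max(max(frames) - offset, 1e-300)
  pages <- lapply(seq_len(dim(frames)[3L]),
                  function(i) (frames[, , i] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  sidecar <- list(
    format = "actinometry_stack",
    scale = scale,
    offset = offset,
    n_frames = dim(frames)[3L],
    timing = list(mode = stack$timing$mode, step_s = stack$timing$step,
                  offset = stack$timing$offset),
    meta = stack$meta[setdiff(names(stack$meta), "field")],
    ground_truth_intensity =
      if (!is.null(stack$meta$field)) stack$meta$field$intensity else NULL
  )
  jsonlite::write_json(sidecar, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an image stack from TIFF (+ sidecar or explicit timing)
#'
#' @param path Multi-page single-channel TIFF path.
#' @param timing Optional [timing_model()]; when absent the sidecar JSON
#'   must provide it.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, timing = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 4L) stop("a stack needs at least 4 frames")
  if (length(dim(pages[[1L]])) != 2L)
    stop("multi-channel (RGB) TIFF not supported; supply a single-channel stack")
  scale <- 1
  offset <- 0
  meta <- list()
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::fromJSON(sc, simplifyDataFrame = FALSE)
    if (!is.null(side$scale)) scale <- side$scale
    if (!is.null(side$offset)) offset <- side$offset
    if (is.null(timing) && !is.null(side$timing)) {
      timing <- timing_model(
        side$timing$mode,
        frame_interval = if (side$timing$mode == "widefield") side$timing$step_s,
        dwell_time = if (side$timing$mode == "raster") side$timing$step_s,
        offset = side$timing$offset
      )
    }
    if (!is.null(side$meta)) meta <- side$meta
  }
  if (is.null(timing))
    stop("timing missing: provide a timing_model or a sidecar JSON")
  frames <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  frames <- frames * scale + offset
  structure(list(frames = frames, times = frames_to_times(length(pages), timing),
                 timing = timing, meta = meta),
            class = "image_stack")
}

#' Write a time series to CSV
#'
#' @param series An `actino_timeseries` (columns `time_s`,
#'   `fluorescence`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("time_s", "fluorescence")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a time series from CSV
#'
#' @param path CSV with columns `time_s`, `fluorescence`.
#' @return An `actino_timeseries`.
#' @export
read_timeseries <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "fluorescence") %in% names(d)))
    stop("time-series CSV needs columns time_s, fluorescence")
  .as_timeseries(d$time_s, d$fluorescence)
}

.write_matrix_tiff <- function(m, path) {
  m[!is.finite(m)] <- 0
  offset <- min(m, 0)
  scale <- max(max(m) - offset, 1e-300)
  tiff::writeTIFF((m - offset) / scale, path, bits.per.sample = 32L,
                  compression = "none")
  c(scale = scale, offset = offset)
}

#' Write analysis results to a directory
#'
#' Writes the standard output bundle for a result object: float TIFF
#' maps, CSV histograms/curves and a JSON summary (parameters,
#' statistics, registry version). Refuses to overwrite existing files
#' unless `force = TRUE`.
#'
#' @param x An `intensity_map`, `tau_map` or `calibration_curve`.
#' @param out_dir Output directory (created if needed).
#' @param force Overwrite existing outputs.
#' @param ... Unused.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(x, out_dir, force = FALSE, ...) UseMethod("write_outputs")

.check_clobber <- function(paths, force) {
  hit <- paths[file.exists(paths)]
  if (!force && length(hit))
    stop(sprintf("outputs exist (%s); use force = TRUE to overwrite",
                 paste(basename(hit), collapse = ", ")))
}

#' @export
write_outputs.intensity_map <- function(x, out_dir, force = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("intensity_map.tif", "intensity_stats.json",
                                "intensity_hist.csv"))
  .check_clobber(paths, force)
  sc <- .write_matrix_tiff(ifelse(x$mask, x$intensity, 0), paths[1L])
  hs <- histogram_stats(x)
  utils::write.csv(hs$histogram, paths[3L], row.names = FALSE)
  jsonlite::write_json(
    list(format = "actinometry_intensity_map", unit = "E m-2 s-1",
         tiff_scale = sc[["scale"]], tiff_offset = sc[["offset"]],
         actinometer = x$actinometer,
         wavelength_nm = x$wavelength_nm, sigma = x$sigma,
         context = x$context, range = c(x$i_min, x$i_max),
         stats = x$stats, registry_version = registry_version()),
    paths[2L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @export
write_outputs.tau_map <- function(x, out_dir, force = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("tau_map.tif", "r_squared.tif", "mask.tif",
                                "tau_stats.json"))
  .check_clobber(paths, force)
  s1 <- .write_matrix_tiff(ifelse(x$mask, x$tau, 0), paths[1L])
  .write_matrix_tiff(ifelse(x$mask, x$r_squared, 0), paths[2L])
  tiff::writeTIFF(x$mask * 1, paths[3L], bits.per.sample = 8L)
  v <- x$tau[x$mask]
  jsonlite::write_json(
    list(format = "actinometry_tau_map", unit = "s",
         tiff_scale = s1[["scale"]], tiff_offset = s1[["offset"]],
         timing = list(mode = x$timing$mode, step_s = x$timing$step,
                       offset = x$timing$offset),
         binning = x$binning, r2_threshold = x$r2_threshold,
         stats = list(n_valid = sum(x$mask), mean = mean(v),
                      median = stats::median(v), sd = stats::sd(v))),
    paths[4L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @export
write_outputs.calibration_curve <- function(x, out_dir, force = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("calibration.csv", "calibration.json"))
  .check_clobber(paths, force)
  utils::write.csv(x$data, paths[1L], row.names = FALSE)
  jsonlite::write_json(
    list(format = "actinometry_calibration",
         slope = x$slope, slope_se = x$slope_se,
         intercept = x$intercept, intercept_se = x$intercept_se,
         r_squared = x$r_squared, origin_consistent = x$origin_consistent),
    paths[2L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
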