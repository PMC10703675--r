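#' Wavelength-gridded spectra
#'
#' An `actino_spectrum` is a curve sampled on a strictly increasing
#' wavelength grid (nm) with nonnegative values, a `kind` tag saying what
#' the curve is (source emission, molar absorption, normalized excitation,
#' photoconversion cross section or an action spectrum) and a
#' `normalization` tag (`"raw"`, `"unit_integral"` for a curve whose
#' trapezoidal integral is 1, or `"unit_at_reference"` for a curve equal to
#' 1 at a reference wavelength `lambda_ref`).
#'
#' @param table A data frame (or two-column matrix) whose first column is
#'   wavelength in nm and second column the spectral value, e.g. as read
#'   from a `wavelength_nm,value` CSV. A file path to such a CSV is also
#'   accepted.
#' @param kind One of `"source_emission"`, `"molar_absorption"`,
#'   `"normalized_excitation"`, `"cross_section"`, `"action"`.
#' @param normalization Normalization to apply: `"raw"` (leave as is),
#'   `"unit_integral"` or `"unit_at_reference"`.
#' @param lambda_ref Reference wavelength (nm), required for
#'   `normalization = "unit_at_reference"`.
#' @return An object of class `actino_spectrum` with fields
#'   `wavelength_nm`, `value`, `kind`, `normalization`, `lambda_ref`.
#' @examples
#' tri <- load_spectrum(data.frame(nm = c(400, 500, 600), v = c(0, 1, 0)),
#'                      kind = "source_emission",
#'                      normalization = "unit_integral")
#' integrate_spectrum(tri)  # 1
#' @export
load_spectrum <- function(table,
                          kind = c("source_emission", "molar_absorption",
                                   "normalized_excitation", "cross_section",
                                   "action"),
                          normalization = c("raw", "unit_integral",
                                            "unit_at_reference"),
                          lambda_ref = NULL) {
  kind <- match.arg(kind)
  normalization <- match.arg(normalization)
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.csv(table)
  }
  table <- as.data.frame(table)
  if (ncol(table) < 2L) stop("spectrum table needs two columns (wavelength_nm, value)")
  wl <- as.numeric(table[[1L]])
  v <- as.numeric(table[[2L]])
  if (length(wl) < 2L) stop("a spectrum needs at least 2 points")
  if (anyNA(wl) || anyNA(v) || any(!is.finite(wl)) || any(!is.finite(v)))
    stop("spectrum contains missing or non-finite values")
  o <- order(wl)
  wl <- wl[o]; v <- v[o]
  if (any(diff(wl) <= 0))
    stop("duplicated wavelengths in spectrum; the grid must be strictly increasing")
  if (any(v < 0)) stop("negative spectral values are not allowed")
  s <- structure(
    list(wavelength_nm = wl, value = v, kind = kind,
         normalization = "raw", lambda_ref = NULL),
    class = "actino_spectrum"
  )
  if (normalization != "raw") s <- normalize_spectrum(s, normalization, lambda_ref)
  s
}

#' Renormalize a spectrum
#'
#' @param s An `actino_spectrum`.
#' @param normalization `"unit_integral"` or `"unit_at_reference"`.
#' @param lambda_ref Reference wavelength (nm) for `"unit_at_reference"`.
#' @return The renormalized spectrum. Renormalizing an already-normalized
#'   spectrum is idempotent.
#' @export
normalize_spectrum <- function(s, normalization = c("unit_integral",
                                                    "unit_at_reference"),
                               lambda_ref = NULL) {
  stopifnot(inherits(s, "actino_spectrum"))
  normalization <- match.arg(normalization)
  if (normalization == "unit_integral") {
    z <- pracma::trapz(s$wavelength_nm, s$value)
    if (z <= 0) stop("cannot normalize a spectrum with zero integral")
    s$value <- s$value / z
    s$normalization <- "unit_integral"
    s$lambda_ref <- NULL
  } else {
    if (is.null(lambda_ref)) stop("lambda_ref is required for unit_at_reference")
    ref <- spectrum_value_at(s, lambda_ref)
    if (ref <= 0) stop("spectrum vanishes at the reference wavelength")
    s$value <- s$value / ref
    s$normalization <- "unit_at_reference"
    s$lambda_ref <- lambda_ref
  }
  s
}

#' Interpolate a spectrum at given wavelengths
#'
#' Linear interpolation within the spectrum's support; no extrapolation.
#'
#' @param s An `actino_spectrum`.
#' @param lambda_nm Wavelengths (nm) inside the support.
#' @return Numeric vector of interpolated values.
#' @export
spectrum_value_at <- function(s, lambda_nm) {
  stopifnot(inherits(s, "actino_spectrum"))
  rng <- range(s$wavelength_nm)
  if (any(lambda_nm < rng[1L] - 1e-9) || any(lambda_nm > rng[2L] + 1e-9))
    stop(sprintf("wavelength outside spectrum support [%g, %g] nm", rng[1L], rng[2L]))
  stats::approx(s$wavelength_nm, s$value, xout = lambda_nm, rule = 1)$y
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto `grid`, which must lie within the spectrum's
#' support (no extrapolation). The `kind` tag is preserved; the
#' normalization tag is downgraded to `"raw"` because resampling does not
#' preserve it exactly - renormalize afterwards if needed.
#'
#' @param s An `actino_spectrum`.
#' @param grid Strictly increasing wavelengths (nm) within the support.
#' @return A resampled `actino_spectrum`.
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "actino_spectrum"))
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with at least 2 points")
  v <- spectrum_value_at(s, grid)
  structure(
    list(wavelength_nm = grid, value = v, kind = s$kind,
         normalization = "raw", lambda_ref = NULL),
    class = "actino_spectrum"
  )
}

#' Trapezoidal integral of a spectrum
#'
#' @param s An `actino_spectrum`.
#' @return The trapezoidal integral over the full support (per-nm values
#'   integrated over nm).
#' @export
integrate_spectrum <- function(s) {
  stopifnot(inherits(s, "actino_spectrum"))
  pracma::trapz(s$wavelength_nm, s$value)
}

#' Write a spectrum to CSV
#'
#' Writes the standard two-column `wavelength_nm,value` format.
#'
#' @param s An `actino_spectrum`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "actino_spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = s$wavelength_nm, value = s$value),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @export
print.actino_spectrum <- function(x, ...) {
  cat(sprintf("<actino_spectrum: %s, %d points, %g-%g nm, normalization %s%s>\n",
              x$kind, length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm),
              x$normalization,
              if (!is.null(x$lambda_ref)) sprintf(" @ %g nm", x$lambda_ref) else ""))
  invisible(x)
}

# common 1-nm grid over the support overlap of two spectra
.common_grid <- function(a, b, step = 1) {
  lo <- max(min(a$wavelength_nm), min(b$wavelength_nm))
  hi <- min(max(a$wavelength_nm), max(b$wavelength_nm))
  if (hi - lo <= 0) stop("spectra have no overlapping support")
  g <- seq(lo, hi, by = step)
  if (g[length(g)] < hi) g <- c(g, hi)
  g
}
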