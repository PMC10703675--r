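#' @title Fluorescent actinometer registry
#' @description
#' The registry holds the tabulated properties of the five fluorescent
#' actinometers: the photoconversion cross section sigma(lambda_exc)
#' (m^2 mol^-1), the range of reliably measurable light intensity
#' (E m^-2 s^-1) and the minimum measurement duration 5*tau_min (s) at each
#' tabulated excitation wavelength, plus the reporting mechanism and
#' emission band. Photon-flux intensity bounds are the authoritative
#' values; energy-unit (W m^-2) bounds are always recomputed with
#' [photon_to_energy()], never stored.
#' @name registry
NULL

.registry_env <- new.env(parent = emptyenv())

.registry_path <- function() {
  system.file("extdata", "actinometers.json", package = "actinometry",
              mustWork = TRUE)
}

.registry <- function() {
  if (is.null(.registry_env$db)) {
    .registry_env$db <- jsonlite::fromJSON(.registry_path(),
                                           simplifyDataFrame = FALSE)
  }
  .registry_env$db
}

#' Version of the bundled actinometer registry
#' @return Character scalar schema version.
#' @export
registry_version <- function() .registry()$schema_version

#' Names of the available actinometers
#' @return Character vector of canonical registry names.
#' @export
list_actinometers <- function() {
  vapply(.registry()$actinometers, `[[`, character(1), "name")
}

.norm_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Load an actinometer record
#'
#' Looks up one actinometer by name (case-insensitive; punctuation-free
#' aliases such as `"dronpa2"` are accepted) and returns its full record:
#' mechanism, emission band, relative uncertainty of sigma, and one entry
#' per tabulated excitation wavelength with sigma, the reliably measurable
#' intensity range and 5*tau_min.
#'
#' @param name Actinometer name: one of `"Cin"`, `"Nit"`, `"Dronpa-2"`,
#'   `"DASA"`, `"PA"` (or an alias).
#' @return An object of class `actinometer` with fields `name`,
#'   `mechanism`, `reversible`, `emission_band_nm`, `sigma_rel_err`,
#'   `kinetic_5tau_rule` and `entries` (a data frame with columns
#'   `lambda_exc_nm`, `sigma`, `sigma_alt`, `i_min`, `i_max`,
#'   `five_tau_min`).
#' @examples
#' cin <- load_actinometer("Cin")
#' nrow(cin$entries)  # 5 tabulated wavelengths
#' @export
load_actinometer <- function(name) {
  db <- .registry()
  key <- .norm_name(name)
  for (rec in db$actinometers) {
    keys <- .norm_name(c(rec$name, unlist(rec$aliases)))
    if (key %in% keys) {
      entries <- do.call(rbind, lapply(rec$entries, function(e) {
        data.frame(
          lambda_exc_nm = e$lambda_exc_nm,
          sigma = e$sigma,
          sigma_alt = if (is.null(e$sigma_alt)) NA_real_ else e$sigma_alt,
          i_min = e$i_min,
          i_max = e$i_max,
          five_tau_min = e$five_tau_min
        )
      }))
      out <- structure(
        list(
          name = rec$name,
          description = rec$description,
          mechanism = rec$mechanism,
          reversible = isTRUE(rec$reversible),
          emission_band_nm = unlist(rec$emission_band_nm),
          sigma_rel_err = rec$sigma_rel_err,
          kinetic_5tau_rule = isTRUE(rec$kinetic_5tau_rule),
          entries = entries,
          cross_section = NULL,
          registry_version = db$schema_version
        ),
        class = "actinometer"
      )
      return(out)
    }
  }
  stop(sprintf("unknown actinometer '%s'; available: %s",
               name, paste(list_actinometers(), collapse = ", ")))
}

#' @export
print.actinometer <- function(x, ...) {
  cat(sprintf("<actinometer %s> mechanism: %s; %s; emission %g-%g nm; sigma +/- %g%%\n",
              x$name, x$mechanism,
              if (x$reversible) "reversible" else "irreversible",
              x$emission_band_nm[1], x$emission_band_nm[2],
              100 * x$sigma_rel_err))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

.match_entry <- function(record, lambda_exc) {
  d <- abs(record$entries$lambda_exc_nm - lambda_exc)
  i <- which(d <= .lambda_match_tol_nm)
  if (length(i) == 0L) {
    stop(sprintf(
      "no tabulated entry for %s at %g nm; tabulated wavelengths: %s nm",
      record$name, lambda_exc,
      paste(record$entries$lambda_exc_nm, collapse = ", ")))
  }
  i[which.min(d[i])]
}

#' Photoconversion cross section at a tabulated wavelength
#'
#' Pure lookup of sigma(lambda_exc); no interpolation between tabulated
#' wavelengths (matching uses a 0.5 nm absolute tolerance). For Dronpa-2
#' the registry carries a second value to be used for labeled bacteria;
#' `context = "bacteria"` selects it where present, and falls back on the
#' solution value with a warning elsewhere.
#'
#' @param record An `actinometer` record.
#' @param lambda_exc Excitation wavelength (nm), must match a tabulated
#'   entry.
#' @param context `"solution"` (also for fixed cells) or `"bacteria"`.
#' @return sigma in m^2 mol^-1.
#' @examples
#' sigma_at(load_actinometer("Cin"), 365)          # 1200
#' sigma_at(load_actinometer("Dronpa-2"), 480, "bacteria")  # 251
#' @export
sigma_at <- function(record, lambda_exc, context = c("solution", "bacteria")) {
  stopifnot(inherits(record, "actinometer"))
  context <- match.arg(context)
  e <- record$entries[.match_entry(record, lambda_exc), ]
  if (context == "bacteria") {
    if (!is.na(e$sigma_alt)) return(e$sigma_alt)
    warning(sprintf("%s has no bacteria-specific sigma at %g nm; using the solution value",
                    record$name, lambda_exc))
  }
  e$sigma
}

#' Check an intensity against an actinometer's reliable range
#'
#' An actinometer only reports intensity faithfully while its light-driven
#' photoconversion step is rate limiting; outside the tabulated range the
#' monoexponential reduction breaks down. This reports whether a measured
#' (or anticipated) intensity falls in the reliable range.
#'
#' @param record An `actinometer` record.
#' @param lambda_exc Tabulated excitation wavelength (nm).
#' @param intensity Intensity in E m^-2 s^-1.
#' @return A list of class `validity_report`: `status` (`"in_range"`,
#'   `"below_range"`, `"above_range"`), `i_min`, `i_max`, and `message`
#'   (for out-of-range, names other registry actinometers covering the
#'   value).
#' @export
validity_check <- function(record, lambda_exc, intensity) {
  stopifnot(inherits(record, "actinometer"), length(intensity) == 1L)
  e <- record$entries[.match_entry(record, lambda_exc), ]
  status <- if (intensity <= 0 || intensity < e$i_min) "below_range"
            else if (intensity > e$i_max) "above_range"
            else "in_range"
  msg <- sprintf("%g E m-2 s-1 is %s for %s at %g nm (reliable range %g-%g)",
                 intensity, gsub("_", " ", status), record$name,
                 e$lambda_exc_nm, e$i_min, e$i_max)
  if (status != "in_range") {
    covering <- Filter(function(nm) {
      r <- load_actinometer(nm)
      any(intensity > r$entries$i_min & intensity <= r$entries$i_max)
    }, setdiff(list_actinometers(), record$name))
    if (length(covering)) {
      msg <- paste0(msg, "; consider: ", paste(covering, collapse = ", "))
    }
  }
  structure(list(status = status, i_min = e$i_min, i_max = e$i_max,
                 lambda_exc_nm = e$lambda_exc_nm, intensity = intensity,
                 message = msg),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(x$message, "\n")
  invisible(x)
}

#' Internal-consistency report for the 5*tau_min rule
#'
#' For actinometers following monoexponential kinetics, the minimum
#' measurement duration satisfies 5*tau_min = 5 / (sigma * I_max) at the
#' highest reliably measurable intensity. This recomputes that value for
#' every tabulated wavelength and compares it with the stored (printed,
#' hence rounded) one. The relative deviation is taken with respect to the
#' exact recomputed value, since the stored value carries rounding error.
#'
#' @param record An `actinometer` record with `kinetic_5tau_rule = TRUE`.
#'   The photosynthetic-apparatus record does not follow the rule (its
#'   tabulated duration is the time needed to record the whole fluorescence
#'   rise) and is rejected.
#' @return A data frame with columns `lambda_exc_nm`,
#'   `five_tau_min_printed`, `five_tau_min_computed`, `rel_deviation`.
#' @examples
#' consistency_report(load_actinometer("Cin"))
#' @export
consistency_report <- function(record) {
  stopifnot(inherits(record, "actinometer"))
  if (!record$kinetic_5tau_rule) {
    stop(sprintf(
      "%s does not follow the 5*tau_min kinetic rule (its tabulated duration is the time needed to record the whole fluorescence rise)",
      record$name))
  }
  e <- record$entries
  computed <- 5 / (e$sigma * e$i_max)
  data.frame(
    lambda_exc_nm = e$lambda_exc_nm,
    five_tau_min_printed = e$five_tau_min,
    five_tau_min_computed = computed,
    rel_deviation = abs(e$five_tau_min - computed) / computed
  )
}

#' Attach a continuous cross-section spectrum to a record
#'
#' The registry tabulates sigma at discrete wavelengths only. For
#' polychromatic (action-spectrum) work a continuous sigma(lambda) curve
#' measured by the user can be attached; it is then available to
#' [effective_sigma()].
#'
#' @param record An `actinometer` record.
#' @param spectrum An `actino_spectrum` of kind `"cross_section"`.
#' @return The record with the spectrum attached.
#' @export
attach_cross_section <- function(record, spectrum) {
  stopifnot(inherits(record, "actinometer"),
            inherits(spectrum, "actino_spectrum"))
  if (spectrum$kind != "cross_section")
    stop("spectrum kind must be 'cross_section'")
  record$cross_section <- spectrum
  record
}
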