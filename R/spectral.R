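#' Convert molar photon flux to energy irradiance
#'
#' A photon at wavelength \eqn{\lambda} carries energy \eqn{hc/\lambda},
#' so a molar photon flux (einstein-based, wavelength-independent) maps to
#' an energy irradiance via
#' \deqn{P = I \cdot \frac{N_A h c}{\lambda}.}
#'
#' @param I_photon Photon flux density in E m^-2 s^-1 (>= 0); vectorized.
#' @param lambda_nm Wavelength in nm (> 0).
#' @return Irradiance in W m^-2.
#' @examples
#' photon_to_energy(1.6e-5, 350)  # ~5.47 W m-2
#' @export
photon_to_energy <- function(I_photon, lambda_nm) {
  if (any(lambda_nm <= 0)) stop("wavelength must be positive")
  if (any(I_photon < 0)) stop("photon flux must be >= 0")
  I_photon * .nahc / (lambda_nm * 1e-9)
}

#' Convert energy irradiance to molar photon flux
#'
#' Exact inverse of [photon_to_energy()].
#'
#' @param P Irradiance in W m^-2 (>= 0); vectorized.
#' @param lambda_nm Wavelength in nm (> 0).
#' @return Photon flux density in E m^-2 s^-1.
#' @export
energy_to_photon <- function(P, lambda_nm) {
  if (any(lambda_nm <= 0)) stop("wavelength must be positive")
  if (any(P < 0)) stop("irradiance must be >= 0")
  P * (lambda_nm * 1e-9) / .nahc
}

#' Transfer a known intensity from one wavelength to another
#'
#' A photochemically inert fluorophore kept below absorbance 0.15 emits
#' fluorescence proportional to the light intensity: \eqn{F_i \propto I_i
#' \epsilon(\lambda_i)}, with the quantum yield cancelling in the ratio.
#' Recording the fluorescence (at one emission wavelength) first under a
#' calibrated source at \eqn{\lambda_1} and then under the unknown source
#' at \eqn{\lambda_2} gives
#' \deqn{I_2 = I_1 \frac{F_2}{F_1}\,\frac{\epsilon(\lambda_1)}{\epsilon(\lambda_2)}.}
#' The result is invariant under a common rescaling of the two
#' fluorescence readings and of the two excitation-spectrum values.
#'
#' @param F1,F2 Fluorescence signals under the calibrated and the unknown
#'   source (same emission wavelength, same units; > 0).
#' @param I1 Known intensity at lambda1 (E m^-2 s^-1).
#' @param eps1,eps2 Excitation-spectrum values of the transfer fluorophore
#'   at the two wavelengths (same normalization; > 0).
#' @return I2 in E m^-2 s^-1.
#' @examples
#' transfer_intensity(F1 = 1, F2 = 2, I1 = 5, eps1 = 1, eps2 = 1)  # 10
#' @export
transfer_intensity <- function(F1, F2, I1, eps1, eps2) {
  vals <- c(F1 = F1, F2 = F2, I1 = I1, eps1 = eps1, eps2 = eps2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all transfer quantities must be positive")
  I1 * (F2 / F1) * (eps1 / eps2)
}

#' Action spectrum of a source on a molecule
#'
#' The wavelength-resolved overlap of a source and a molecular response:
#' the pointwise product of the source's unit-integral emission spectrum
#' with the molecule's excitation (or cross-section) spectrum, on a
#' common 1-nm grid over the overlapping support. Note this "convolution"
#' in the photochemical sense is an overlap product followed by
#' integration, not a shift-convolution.
#'
#' @param source An `actino_spectrum`; renormalized to unit integral if
#'   it is not already.
#' @param response An `actino_spectrum` (excitation spectrum or cross
#'   section).
#' @param step Common grid step in nm (default 1).
#' @return An `actino_spectrum` of kind `"action"` on the overlap grid.
#' @export
action_spectrum <- function(source, response, step = 1) {
  stopifnot(inherits(source, "actino_spectrum"),
            inherits(response, "actino_spectrum"))
  g <- .common_grid(source, response, step)
  s <- resample_spectrum(source, g)
  if (source$normalization != "unit_integral")
    s <- normalize_spectrum(s, "unit_integral")
  r <- resample_spectrum(response, g)
  structure(
    list(wavelength_nm = g, value = s$value * r$value, kind = "action",
         normalization = "raw", lambda_ref = NULL),
    class = "actino_spectrum"
  )
}

#' Effective cross section under a polychromatic source
#'
#' Weights a wavelength-resolved photoconversion cross section by the
#' source's normalized emission spectrum:
#' \deqn{\sigma_{eff} = \int \sigma(\lambda)\, s_{norm}(\lambda)\, d\lambda,}
#' so that an actinometer measured under the polychromatic source obeys
#' \eqn{S_I = 1/(\sigma_{eff}\,\tau)} for the integral photon flux
#' \eqn{S_I}. For a source much narrower than the cross-section spectrum
#' this reduces to the monochromatic \eqn{\sigma(\lambda_0)}.
#'
#' @param sigma_spectrum An `actino_spectrum` of kind `"cross_section"`
#'   (m^2 mol^-1 values).
#' @param source Source emission `actino_spectrum` (renormalized to unit
#'   integral if needed).
#' @param step Common grid step in nm.
#' @return Effective sigma in m^2 mol^-1.
#' @export
effective_sigma <- function(sigma_spectrum, source, step = 1) {
  a <- action_spectrum(source, sigma_spectrum, step)
  pracma::trapz(a$wavelength_nm, a$value)
}

#' Spectral intensity of a polychromatic source via fluorescence transfer
#'
#' Extends the two-wavelength transfer to a broadband source. The
#' transfer fluorophore is first read under an effectively monochromatic
#' reference at \eqn{\lambda_{ref}} with known intensity `I_ref`, then
#' under the polychromatic source. With the fluorophore's excitation
#' spectrum normalized to 1 at \eqn{\lambda_{ref}} and the source
#' emission normalized to unit integral, the integral photon flux of the
#' source is
#' \deqn{S_I = \frac{F_{target}/F_{ref}\; I_{ref}}
#'   {\int s_{norm}(\lambda)\,\epsilon_{norm}(\lambda)\,d\lambda},}
#' and its spectral intensity is \eqn{I(\lambda) = S_I\, s_{norm}(\lambda)}.
#' If the reference source has a non-negligible bandwidth, pass its
#' spectrum as `ref_source`; the numerator is then weighted by the
#' reference's own overlap integral instead of treating it as a line at
#' \eqn{\lambda_{ref}}.
#'
#' @param F_ratio Ratio of fluorescence under the target source to
#'   fluorescence under the reference (> 0).
#' @param I_ref Known reference intensity (E m^-2 s^-1).
#' @param eps_norm Excitation spectrum of the transfer fluorophore,
#'   normalized to 1 at `lambda_ref` (`unit_at_reference`).
#' @param source Target source emission spectrum (unit integral; will be
#'   renormalized if raw).
#' @param ref_source Optional reference-source emission spectrum; default
#'   NULL treats the reference as monochromatic at `eps_norm$lambda_ref`.
#' @param step Common grid step in nm.
#' @return An object of class `spectral_intensity`: `S_I` (E m^-2 s^-1),
#'   `shape` (unit-integral source spectrum), `I_lambda` (spectrum of
#'   per-nm intensity `S_I * shape`), and the overlap integral used.
#' @export
polychromatic_transfer <- function(F_ratio, I_ref, eps_norm, source,
                                   ref_source = NULL, step = 1) {
  stopifnot(inherits(eps_norm, "actino_spectrum"),
            inherits(source, "actino_spectrum"))
  if (F_ratio <= 0 || I_ref <= 0) stop("F_ratio and I_ref must be positive")
  if (eps_norm$normalization != "unit_at_reference")
    stop("eps_norm must be normalized to 1 at the reference wavelength (unit_at_reference)")
  a <- action_spectrum(source, eps_norm, step)
  overlap <- pracma::trapz(a$wavelength_nm, a$value)
  if (overlap <= 0) stop("vanishing overlap between source and excitation spectrum")
  ref_factor <- 1
  if (!is.null(ref_source)) {
    ar <- action_spectrum(ref_source, eps_norm, step)
    ref_factor <- pracma::trapz(ar$wavelength_nm, ar$value)
    if (ref_factor <= 0) stop("vanishing overlap for the reference source")
  }
  S_I <- F_ratio * I_ref * ref_factor / overlap
  shape <- if (source$normalization == "unit_integral") source
           else normalize_spectrum(source, "unit_integral")
  I_lambda <- shape
  I_lambda$value <- S_I * shape$value
  I_lambda$kind <- "source_emission"
  I_lambda$normalization <- "raw"
  structure(list(S_I = S_I, shape = shape, I_lambda = I_lambda,
                 overlap_integral = overlap, ref_factor = ref_factor),
            class = "spectral_intensity")
}

#' @export
print.spectral_intensity <- function(x, ...) {
  cat(sprintf("<spectral_intensity: S_I = %.4g E m-2 s-1 (overlap integral %.4g)>\n",
              x$S_I, x$overlap_integral))
  invisible(x)
}
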