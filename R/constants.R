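#' Physical constants used for photon/energy conversion
#'
#' Returns the 2019 SI exact values of the Avogadro constant, the Planck
#' constant and the speed of light, together with their product
#' \eqn{N_A h c} (J m mol\eqn{^{-1}}), which converts a molar photon flux at
#' wavelength \eqn{\lambda} into an energy flux.
#'
#' @return A named list with elements `N_A` (mol^-1), `h` (J s),
#'   `c` (m s^-1) and `N_A_h_c` (J m mol^-1).
#' @examples
#' photon_constants()$N_A_h_c  # 0.1196266 J m / mol
#' @export
photon_constants <- function() {
  list(
    N_A = 6.02214076e23,
    h = 6.62607015e-34,
    c = 2.99792458e8,
    N_A_h_c = 6.02214076e23 * 6.62607015e-34 * 2.99792458e8
  )
}

# single internal source of truth for N_A * h * c
.nahc <- 6.02214076e23 * 6.62607015e-34 * 2.99792458e8

# absolute tolerance (nm) for matching tabulated excitation wavelengths
.lambda_match_tol_nm <- 0.5
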