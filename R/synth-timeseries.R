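#' Noise model for simulated fluorescence data
#'
#' @param kind `"none"`, `"gaussian_additive"` (zero-mean Gaussian with
#'   standard deviation `scale` times the reference signal level) or
#'   `"shot_like"` (scaled Poisson draws; `scale` is the relative shot
#'   noise at the reference level, i.e. the effective photon count per
#'   reference unit is `1/scale^2`).
#' @param scale Nonnegative noise scale, as a fraction of the reference
#'   (initial) signal. Default 0.01 (1 percent).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   realizations. The global RNG state is left untouched.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "gaussian_additive", "shot_like"),
                        scale = 0.01, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(scale) || scale < 0) stop("noise scale must be >= 0")
  structure(list(kind = kind, scale = scale, seed = seed),
            class = "noise_model")
}

# run expr with a locally-seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# apply a noise model to a numeric vector/array; ref is the signal level
# that scale is a fraction of
.apply_noise <- function(x, noise, ref) {
  if (is.null(noise) || noise$kind == "none" || noise$scale == 0) return(x)
  .with_seed(noise$seed, {
    if (noise$kind == "gaussian_additive") {
      x + stats::rnorm(length(x), sd = noise$scale * ref)
    } else {
      gain <- 1 / (noise$scale^2 * ref)   # counts per signal unit at ref level
      y <- stats::rpois(length(x), lambda = pmax(x, 0) * gain) / gain
      if (is.null(dim(x))) y else array(y, dim = dim(x))
    }
  })
}

.check_times <- function(times) {
  if (length(times) == 0L) stop("empty time vector")
  if (anyNA(times) || any(!is.finite(times))) stop("non-finite times")
  if (times[1L] < 0) stop("times must start at t >= 0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  as.numeric(times)
}

.as_timeseries <- function(time_s, fluorescence) {
  structure(data.frame(time_s = time_s, fluorescence = fluorescence),
            class = c("actino_timeseries", "data.frame"))
}

#' Simulate a monoexponential photoconversion time series
#'
#' Forward model of the basic actinometry experiment: a jump of constant
#' light drives the actinometer toward its photostationary (or fully
#' converted) state, and the fluorescence follows
#' \deqn{F(t) = F_\infty + (F_0 - F_\infty) e^{-t/\tau}}
#' with \eqn{\tau = 1/(\sigma I)}. A decaying curve has
#' \eqn{F_0 > F_\infty}; a rising one (dark-to-bright photoconversion) has
#' \eqn{F_0 < F_\infty}.
#'
#' @param tau Characteristic time in seconds (> 0).
#' @param F0 Initial fluorescence signal (>= 0).
#' @param F_inf Plateau signal (>= 0; 0 for a fully irreversible dark
#'   product, > 0 for a reversible photostationary state or incomplete
#'   contrast). Must differ from `F0`.
#' @param times Strictly increasing sampling times (s), starting at t >= 0.
#' @param noise A [noise_model()]; the reference level for the noise scale
#'   is `max(F0, F_inf)`.
#' @return An `actino_timeseries` data frame with columns `time_s`,
#'   `fluorescence`.
#' @examples
#' ts <- simulate_timeseries(tau = 0.63, F0 = 1, F_inf = 0.2,
#'                           times = seq(0, 5, 0.01))
#' head(ts)
#' @export
simulate_timeseries <- function(tau, F0, F_inf = 0, times,
                                noise = noise_model("none")) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (F0 < 0 || F_inf < 0) stop("F0 and F_inf must be >= 0")
  if (F0 == F_inf) stop("F0 must differ from F_inf (no kinetics otherwise)")
  times <- .check_times(times)
  f <- F_inf + (F0 - F_inf) * exp(-times / tau)
  f <- .apply_noise(f, noise, ref = max(F0, F_inf))
  .as_timeseries(times, f)
}

#' Simulate an inner-filter-reported photoconversion time series
#'
#' When the actinometer and its photoproduct are both nonfluorescent, a
#' photochemically inert reporter fluorophore is co-dissolved and its
#' fluorescence reports on the sample absorbance at the excitation
#' wavelength through the inner filter effect. The absorbance relaxes as
#' \eqn{A(t) = A_\infty + (A_0 - A_\infty) e^{-t/\tau}} and the reporter
#' signal follows the path-averaged attenuation factor
#' \deqn{F(t) = F_{rep} \frac{1 - 10^{-A(t)}}{A(t) \ln 10},}
#' which tends to `reporter_level` as the absorbance vanishes. The working
#' absorbance is best kept around 0.15 for sensitivity while keeping the
#' excitation nearly constant along the path; values above 0.15 trigger a
#' warning and above 0.3 an error.
#'
#' @param A0 Initial absorbance at the excitation wavelength (0-0.3).
#' @param A_inf Final absorbance (0 <= A_inf <= A0; equality gives a
#'   constant signal).
#' @param tau Characteristic time (s).
#' @param reporter_level Reporter fluorescence in the zero-absorbance
#'   limit (arbitrary units).
#' @param times Sampling times (s).
#' @param noise A [noise_model()].
#' @return An `actino_timeseries`.
#' @export
simulate_inner_filter_series <- function(A0, A_inf = 0, tau, reporter_level = 1,
                                         times, noise = noise_model("none")) {
  if (A0 < 0 || A_inf < 0) stop("absorbances must be >= 0")
  if (A0 < A_inf) stop("A0 must be >= A_inf (photoconversion lowers the absorbance)")
  if (A0 > 0.3) stop("A0 above 0.3: excitation is no longer nearly constant along the path")
  if (A0 > 0.15) warning("A0 above 0.15: the working absorbance is best adjusted around 0.15")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  times <- .check_times(times)
  A <- A_inf + (A0 - A_inf) * exp(-times / tau)
  # -expm1(-A ln10) / (A ln10) is the cancellation-safe form of
  # (1 - 10^-A) / (A ln10)
  att <- ifelse(A > 0, -expm1(-A * log(10)) / (A * log(10)), 1)
  f <- reporter_level * att
  f <- .apply_noise(f, noise, ref = reporter_level)
  .as_timeseries(times, f)
}

#' Simulate the photosynthetic-apparatus fluorescence rise
#'
#' On a jump of constant light, the fluorescence of dark-adapted
#' photosynthetic organisms rises from a minimum to a maximum through
#' intermediate phases in under a second. The fastest phase's rate
#' constant is proportional to light intensity, \eqn{k_1 = \sigma_{PA} I};
#' the slower phases are lumped into a single second exponential with rate
#' \eqn{k_2 = } `slow_ratio` \eqn{\times k_1}:
#' \deqn{F(t) = F_O + A_1 (1 - e^{-k_1 t}) + A_2 (1 - e^{-k_2 t}).}
#'
#' @param I Light intensity (E m^-2 s^-1), within the photosynthetic
#'   apparatus' reliable range (0, 1e-2].
#' @param sigma_pa Cross section of the fastest step (m^2 mol^-1),
#'   default the tabulated blue-light value 2.0e6.
#' @param amplitudes Numeric `c(F_O, A1, A2)`: minimal fluorescence and
#'   the amplitudes of the fast and slow phases.
#' @param slow_ratio Ratio k2/k1 (< 0.2 so the phases stay separable).
#' @param times Sampling times (s).
#' @param noise A [noise_model()].
#' @return An `actino_timeseries`.
#' @examples
#' ts <- simulate_pa_rise(I = 1e-2, times = seq(0, 5e-4, 2e-6))
#' @export
simulate_pa_rise <- function(I, sigma_pa = 2.0e6,
                             amplitudes = c(F_O = 0.2, A1 = 0.6, A2 = 0.2),
                             slow_ratio = 0.05, times,
                             noise = noise_model("none")) {
  pa <- load_actinometer("PA")
  if (I <= 0 || I > max(pa$entries$i_max))
    stop(sprintf("I must lie in the photosynthetic apparatus' reliable range (0, %g] E m-2 s-1",
                 max(pa$entries$i_max)))
  if (slow_ratio < 0 || slow_ratio >= 0.2)
    stop("slow_ratio must be in [0, 0.2) for the phases to remain separable")
  if (length(amplitudes) != 3L || any(amplitudes < 0))
    stop("amplitudes must be c(F_O, A1, A2), all >= 0")
  times <- .check_times(times)
  k1 <- sigma_pa * I
  k2 <- slow_ratio * k1
  F_O <- amplitudes[[1L]]; A1 <- amplitudes[[2L]]; A2 <- amplitudes[[3L]]
  f <- F_O + A1 * (1 - exp(-k1 * times)) + A2 * (1 - exp(-k2 * times))
  f <- .apply_noise(f, noise, ref = F_O + A1 + A2)
  .as_timeseries(times, f)
}

#' Simulate an LED-like source emission spectrum
#'
#' Builds a sum of Gaussian emission bands on a 1-nm grid spanning three
#' FWHM beyond the outermost peaks, normalized to unit integral. A
#' white-LED-like source is e.g. a narrow blue peak plus a broad phosphor
#' band.
#'
#' @param peaks Data frame (or list of rows) with columns `center_nm`,
#'   `fwhm_nm`, `weight`.
#' @return An `actino_spectrum` of kind `"source_emission"`, unit
#'   integral.
#' @examples
#' white <- simulate_source_spectrum(data.frame(
#'   center_nm = c(450, 550), fwhm_nm = c(20, 100), weight = c(1, 1.6)))
#' @export
simulate_source_spectrum <- function(peaks) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) < 1L) stop("at least one peak is required")
  if (any(peaks$fwhm_nm <= 0) || any(peaks$weight <= 0))
    stop("peak widths and weights must be positive")
  lo <- floor(min(peaks$center_nm - 3 * peaks$fwhm_nm))
  hi <- ceiling(max(peaks$center_nm + 3 * peaks$fwhm_nm))
  grid <- seq(lo, hi, by = 1)
  v <- rep(0, length(grid))
  for (i in seq_len(nrow(peaks))) {
    sd <- peaks$fwhm_nm[i] / (2 * sqrt(2 * log(2)))
    v <- v + peaks$weight[i] * exp(-(grid - peaks$center_nm[i])^2 / (2 * sd^2))
  }
  load_spectrum(data.frame(wavelength_nm = grid, value = v),
                kind = "source_emission", normalization = "unit_integral")
}
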