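#' Per-pixel monoexponential fitting of an image stack
#'
#' Fits the monoexponential kinetic model independently at every pixel of
#' a fluorescence stack (optionally after k x k binning), using
#' [frames_to_times()] for the exposure-time axis. Each pixel goes through
#' the same fitting core as [fit_monoexp()]; pixels whose fit fails (no
#' detectable kinetics) or whose r^2 falls below the threshold are masked,
#' not dropped. For raster-scanned solution samples, restrict the analysis
#' to a central portion of the image with `roi_fraction` to limit the
#' interference of molecular diffusion.
#'
#' @param stack An `image_stack` (from [simulate_stack()] or
#'   [read_stack()]).
#' @param timing A [timing_model()]; defaults to the stack's own.
#' @param binning Integer k for k x k pixel binning before fitting
#'   (default 1, none).
#' @param r2_threshold Minimum r^2 for a pixel to be kept (default 0.9).
#' @param roi Optional list(rows =, cols =) of index ranges to fit.
#' @param roi_fraction Optional central-ROI linear fraction (e.g. 1/3
#'   keeps the central third in each dimension); overrides `roi`.
#' @param fix_plateau Optional fixed plateau for a 2-parameter fit.
#' @return An object of class `tau_map`: matrices `tau` (s, NA where
#'   masked), `r_squared`, `F0`, `F_inf`, logical `mask` (TRUE = valid),
#'   and `timing` provenance. Errors when every pixel is masked.
#' @examples
#' f <- make_intensity_field("uniform", c(8, 8), I = 5)
#' st <- simulate_stack(f, sigma = 198, n_frames = 16,
#'                      timing = timing_model("widefield", frame_interval = 2e-4))
#' tm <- fit_stack(st)
#' range(tm$tau)
#' @export
fit_stack <- function(stack, timing = NULL, binning = 1L, r2_threshold = 0.9,
                      roi = NULL, roi_fraction = NULL, fix_plateau = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(timing)) timing <- stack$timing
  frames <- stack$frames
  d <- dim(frames)
  if (d[3L] < 4L) stop("at least 4 frames are required")
  times <- frames_to_times(d[3L], timing)

  if (!is.null(roi_fraction)) roi <- central_roi(d[1:2], roi_fraction)
  if (!is.null(roi)) frames <- frames[roi$rows, roi$cols, , drop = FALSE]

  binning <- as.integer(binning)
  if (binning > 1L) frames <- .bin_stack(frames, binning)
  h <- dim(frames)[1L]; w <- dim(frames)[2L]; nf <- dim(frames)[3L]

  tau <- r2 <- f0 <- finf <- matrix(NA_real_, h, w)
  mask <- matrix(FALSE, h, w)
  ymat <- matrix(aperm(frames, c(3L, 1L, 2L)), nrow = nf)  # frames x pixels
  for (p in seq_len(h * w)) {
    core <- tryCatch(.monoexp_core(times, ymat[, p], fix_plateau),
                     error = function(e) NULL)
    if (!is.null(core) && is.finite(core$r_squared) &&
        core$r_squared >= r2_threshold) {
      i <- (p - 1L) %% h + 1L; j <- (p - 1L) %/% h + 1L
      tau[i, j] <- core$tau
      r2[i, j] <- core$r_squared
      f0[i, j] <- core$F0
      finf[i, j] <- core$F_inf
      mask[i, j] <- TRUE
    }
  }
  if (!any(mask)) stop("no fittable signal: every pixel was masked")
  structure(
    list(tau = tau, r_squared = r2, F0 = f0, F_inf = finf, mask = mask,
         timing = timing, binning = binning, r2_threshold = r2_threshold,
         pixel_size_m = stack$meta$pixel_size_m * binning),
    class = "tau_map"
  )
}

#' Central rectangular region of interest
#'
#' Index helper implementing the central-portion restriction used for
#' raster-scanned solution measurements, where molecular diffusion from
#' outside the scanned field perturbs the edges most.
#'
#' @param dim Integer `c(nrow, ncol)`.
#' @param fraction Linear fraction of each dimension to keep, centered
#'   (default 1/3).
#' @return `list(rows =, cols =)` of integer index vectors.
#' @export
central_roi <- function(dim, fraction = 1 / 3) {
  stopifnot(fraction > 0, fraction <= 1)
  mid <- function(n) {
    k <- max(1L, round(n * fraction))
    s <- max(1L, floor((n - k) / 2) + 1L)
    s:(s + k - 1L)
  }
  list(rows = mid(dim[1L]), cols = mid(dim[2L]))
}

# k x k block-mean binning of an H x W x n array (truncates remainders)
.bin_stack <- function(frames, k) {
  d <- dim(frames)
  h <- (d[1L] %/% k) * k; w <- (d[2L] %/% k) * k
  frames <- frames[seq_len(h), seq_len(w), , drop = FALSE]
  hb <- h %/% k; wb <- w %/% k
  out <- array(0, dim = c(hb, wb, d[3L]))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out <- out + frames[seq(i, h, by = k), seq(j, w, by = k), , drop = FALSE]
  }
  out / (k * k)
}

#' @export
print.tau_map <- function(x, ...) {
  v <- x$tau[x$mask]
  cat(sprintf("<tau_map: %d x %d px, %d/%d valid, tau %g-%g s (median %g)>\n",
              nrow(x$tau), ncol(x$tau), sum(x$mask), length(x$mask),
              min(v), max(v), stats::median(v)))
  invisible(x)
}

#' Fastest rate constant of the photosynthetic fluorescence rise
#'
#' Fits the two-exponential rise
#' \eqn{F(t) = F_O + A_1(1 - e^{-k_1 t}) + A_2(1 - e^{-k_2 t})} and
#' returns the fast rate \eqn{k_1}, which is proportional to light
#' intensity (\eqn{k_1 = \sigma_{PA} I}). Starting values come from a
#' single-exponential fit; if the two-component fit fails or collapses,
#' the fallback is a single-exponential fit restricted to the early
#' window (the first \eqn{3/k_1} estimate), where the slow phase
#' contributes least.
#'
#' @inheritParams fit_monoexp
#' @return The fast rate constant k1 in s^-1.
#' @examples
#' ts <- simulate_pa_rise(I = 1e-2, amplitudes = c(0.2, 0.8, 0),
#'                        times = seq(0, 5e-4, 2.5e-6))
#' fit_pa_fastest_rate(ts)  # ~2e4
#' @export
fit_pa_fastest_rate <- function(series, fluorescence = NULL) {
  d <- .coerce_series(series, fluorescence)
  if (detect_direction(series, fluorescence) != "rise")
    stop("the photosynthetic-apparatus analysis requires a rising series")
  single <- .monoexp_core(d$t, d$y)
  k_est <- 1 / single$tau

  early <- d$t - d$t[1L] <= 3 / k_est
  if (sum(early) < 10L)
    warning("fewer than 10 points within the estimated fast phase; k1 may be poorly constrained")

  amp <- max(d$y) - min(d$y)
  two <- tryCatch({
    df <- data.frame(t = d$t, y = d$y)
    fit <- minpack.lm::nlsLM(
      y ~ F_O + A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t)),
      data = df,
      start = list(F_O = min(d$y), A1 = 0.7 * amp, A2 = 0.3 * amp,
                   k1 = k_est, k2 = 0.05 * k_est),
      lower = c(F_O = 0, A1 = 0, A2 = 0, k1 = 0, k2 = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    k1 <- max(cf[["k1"]], cf[["k2"]])
    a_fast <- if (cf[["k1"]] >= cf[["k2"]]) cf[["A1"]] else cf[["A2"]]
    if (!is.finite(k1) || k1 <= 0 || a_fast <= 0.05 * amp) NULL else k1
  }, error = function(e) NULL)
  if (!is.null(two)) return(two)

  # degenerate two-component fit: single exponential on the early window
  if (sum(early) >= 4L) {
    early_fit <- tryCatch(.monoexp_core(d$t[early], d$y[early]),
                          error = function(e) NULL)
    if (!is.null(early_fit)) return(1 / early_fit$tau)
  }
  1 / single$tau
}
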