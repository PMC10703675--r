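#' Exposure-timing model for image stacks
#'
#' Describes how frame index maps to cumulative illumination time per
#' pixel. In wide-field mode every pixel of frame n has seen
#' `n * frame_interval` of light; in raster (confocal) scanning every
#' pixel is illuminated for exactly one dwell time per frame regardless of
#' its position in the scan, so the cumulative illuminated time after n
#' frames is `n * dwell_time`. The `offset` convention assigns the frame's
#' signal either to the start of its exposure (default) or to its
#' midpoint.
#'
#' @param mode `"widefield"` or `"raster"`.
#' @param frame_interval Frame interval in seconds (wide-field mode).
#' @param dwell_time Per-pixel dwell time in seconds per frame (raster
#'   mode).
#' @param offset `"start"` or `"midpoint"`.
#' @return An object of class `timing_model`.
#' @examples
#' timing_model("raster", dwell_time = 2e-6)
#' @export
timing_model <- function(mode = c("widefield", "raster"),
                         frame_interval = NULL, dwell_time = NULL,
                         offset = c("start", "midpoint")) {
  mode <- match.arg(mode)
  offset <- match.arg(offset)
  step <- if (mode == "widefield") frame_interval else dwell_time
  if (is.null(step) || !is.finite(step) || step <= 0) {
    stop(sprintf("%s timing requires a positive %s", mode,
                 if (mode == "widefield") "frame_interval" else "dwell_time"))
  }
  structure(list(mode = mode, step = step, offset = offset),
            class = "timing_model")
}

#' @export
print.timing_model <- function(x, ...) {
  cat(sprintf("<timing_model %s: %g s per frame, %s convention>\n",
              x$mode, x$step, x$offset))
  invisible(x)
}

#' Cumulative illumination times for a frame sequence
#'
#' Converts a number of frames into the cumulative illuminated time per
#' pixel at each frame, under the given timing model. Frames are indexed
#' from 0, so with the `"start"` convention `t_n = n * step` and with
#' `"midpoint"` `t_n = n * step + step / 2`.
#'
#' @param n_frames Number of frames (>= 4; a 3-parameter monoexponential
#'   fit is under-determined below that).
#' @param timing A [timing_model()].
#' @return Numeric vector of `n_frames` times in seconds.
#' @examples
#' frames_to_times(5, timing_model("raster", dwell_time = 2e-6))
#' @export
frames_to_times <- function(n_frames, timing) {
  stopifnot(inherits(timing, "timing_model"))
  if (n_frames < 4L)
    stop("at least 4 frames are required for a 3-parameter monoexponential fit")
  t <- (seq_len(n_frames) - 1) * timing$step
  if (timing$offset == "midpoint") t <- t + timing$step / 2
  t
}
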