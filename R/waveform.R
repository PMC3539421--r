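#' Phasic inlet pressure waveform
#'
#' The inlet drive is a non-negative gauge pressure, zero at cycle
#' boundaries and peaking at mid-cycle:
#' \deqn{P(t) = A \sin^2(\pi (t - t_0) / T).}
#' The default period is 4 s (a resting breathing cycle); the default
#' amplitude 300 Pa is a plausible spirometry-scale driving pressure and is
#' fully configurable.
#'
#' @param amplitude Peak gauge pressure (Pa), >= 0.  Default 300.
#' @param period Cycle period (s), > 0.  Default 4.
#' @param phase_offset Time shift (s).  Default 0.
#' @param shape Waveform shape; only \code{"sinusoidal"} is defined.
#' @return An object of class \code{waveform}.
#' @export
waveform <- function(amplitude = 300, period = 4, phase_offset = 0,
                     shape = "sinusoidal") {
  shape <- match.arg(shape, "sinusoidal")
  if (!is.numeric(period) || period <= 0) stop("'period' must be > 0")
  if (!is.numeric(amplitude) || amplitude < 0) stop("'amplitude' must be >= 0")
  structure(list(amplitude = amplitude, period = period,
                 phase_offset = phase_offset, shape = shape),
            class = "waveform")
}

#' Evaluate the inlet pressure waveform
#'
#' @param w A [waveform()].
#' @param t Time(s) in seconds, vectorized.
#' @return Gauge pressure (Pa): zero at cycle boundaries, equal to the
#'   amplitude at mid-cycle (\code{t = period/2} for zero phase offset).
#' @examples
#' w <- waveform(amplitude = 300, period = 4)
#' waveform_value(w, c(0, 2, 4))  # 0, 300, 0
#' @export
waveform_value <- function(w, t) {
  stopifnot(inherits(w, "waveform"))
  w$amplitude * sin(pi * (t - w$phase_offset) / w$period)^2
}

#' @export
print.waveform <- function(x, ...) {
  cat("Phasic inlet waveform: amplitude", x$amplitude, "Pa, period",
      x$period, "s, phase offset", x$phase_offset, "s (sin^2)\n")
  invisible(x)
}

# mid-cycle drive peak time of cycle `cycle` (1-based)
drive_peak_time <- function(w, cycle) {
  w$phase_offset + (cycle - 1) * w$period + w$period / 2
}
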