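#' Analytic signal via the DFT construction
#'
#' Computes `x + i * H{x}` for a finite record of period `R = length(x)`
#' by spectral weighting of the DFT: DC is kept, positive frequencies are
#' doubled, negative frequencies are zeroed, and for even `R` the Nyquist
#' bin is kept as well (the even/odd distinction in the discrete Hilbert
#' transform). The imaginary part is the discrete Hilbert transform of the
#' input.
#'
#' @param signal An [hl_signal()] or numeric vector (with `rate`).
#' @param rate Sampling rate if `signal` is a bare vector.
#' @return An object of class `hl_analytic`: list with `real_part`,
#'   `imag_part`, `rate`, `n`.
#' @export
analytic_signal <- function(signal, rate = NULL) {
  signal <- as_hl_signal(signal, rate)
  x <- signal$samples
  R <- length(x)
  if (R < 2L)
    stop("analytic signal needs at least 2 samples", call. = FALSE)
  Y <- stats::fft(x)
  h <- numeric(R)
  if (R %% 2L == 0L) {
    h[1] <- 1; h[R / 2 + 1] <- 1
    if (R > 2) h[2:(R / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((R + 1) / 2)] <- 2
  }
  z <- stats::fft(Y * h, inverse = TRUE) / R
  structure(list(real_part = Re(z), imag_part = Im(z),
                 rate = signal$rate, n = R),
            class = "hl_analytic")
}

#' Hilbert envelope of a signal
#'
#' The magnitude of the analytic signal, `sqrt(x^2 + H{x}^2)`. It bounds
#' the waveform from above pointwise and, for a narrow-band tone, equals
#' its amplitude.
#'
#' @inheritParams analytic_signal
#' @return An object of class `hl_envelope`: list with nonnegative
#'   `values`, `rate`, `n` and logical `smoothed`.
#' @export
hilbert_envelope <- function(signal, rate = NULL) {
  a <- analytic_signal(signal, rate)
  structure(list(values = sqrt(a$real_part^2 + a$imag_part^2),
                 rate = a$rate, n = a$n, smoothed = FALSE),
            class = "hl_envelope")
}

#' Instantaneous phase of an analytic signal
#'
#' @param analytic An `hl_analytic` from [analytic_signal()].
#' @return Phase angles in radians, in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(analytic) {
  stopifnot(inherits(analytic, "hl_analytic"))
  atan2(analytic$imag_part, analytic$real_part)
}

#' Smooth an envelope with a low-pass Butterworth filter
#'
#' Removes the fast lung-sound ripple so that the surviving extrema
#' correspond to whole acoustic events. Applied zero-phase by default so
#' the extrema are not delayed. Negative values produced by filter ringing
#' are clamped to 0 (envelopes are nonnegative by definition; the clamp
#' only touches ringing around silence).
#'
#' @param env An `hl_envelope` (unsmoothed).
#' @param cutoff_hz Smoothing cutoff in Hz; the method's operating range
#'   is 7--25 Hz (default 15). Lower cutoffs widen detected events.
#' @param order Butterworth order (default 5).
#' @param mode `"zerophase"` or `"single"` pass.
#' @return A smoothed `hl_envelope`.
#' @export
smooth_envelope <- function(env, cutoff_hz = 15, order = 5,
                            mode = c("zerophase", "single")) {
  stopifnot(inherits(env, "hl_envelope"))
  mode <- match.arg(mode)
  if (isTRUE(env$smoothed))
    stop("envelope is already smoothed", call. = FALSE)
  sos <- butter_lowpass(order, cutoff_hz, env$rate)
  v <- if (mode == "zerophase") sos_filtfilt(sos, env$values)
       else sos_filter(sos, env$values)
  structure(list(values = pmax(v, 0), rate = env$rate, n = env$n,
                 smoothed = TRUE),
            class = "hl_envelope")
}

#' @export
print.hl_envelope <- function(x, ...) {
  cat(sprintf("<hl_envelope> %d samples @ %g Hz, %s, max %.4g\n",
              x$n, x$rate, if (x$smoothed) "smoothed" else "raw",
              max(x$values)))
  invisible(x)
}
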