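#' Amplitude normalization
#'
#' Divides the waveform by its absolute maximum `M`, mapping it into
#' `[-1, 1]` with at least one sample at +/-1. Removes inter-recording
#' gain differences (instrument gain, auscultation site, subject) so the
#' downstream threshold sees comparable envelope magnitudes. Idempotent
#' and invariant to positive rescaling of the input.
#'
#' @param signal An [hl_signal()].
#' @return An `hl_signal` with attribute `M` (the absolute maximum of the
#'   input, recorded for traceability).
#' @export
normalize_amplitude <- function(signal) {
  signal <- as_hl_signal(signal)
  M <- max(abs(signal$samples))
  if (M == 0)
    stop("cannot normalize an all-zero signal (no scale exists)",
         call. = FALSE)
  out <- hl_signal(signal$samples / M, signal$rate)
  attr(out, "M") <- M
  out
}

#' Low-pass filtering to enhance heart-sound components
#'
#' Attenuates the broadband lung-sound and murmur energy above the
#' cardiac band with a Butterworth low-pass (default: order 10, 150 Hz
#' cutoff). Zero-phase application (the default) squares the magnitude
#' response (-6 dB at the cutoff instead of -3 dB) but introduces no
#' group delay, so event boundaries are not shifted.
#'
#' @param signal An [hl_signal()].
#' @param cutoff_hz Cutoff in Hz, must be below `rate/2` (default 150).
#' @param order Butterworth order (default 10).
#' @param mode `"zerophase"` (default) or `"single"` causal pass.
#' @return Filtered `hl_signal` of identical length and rate.
#' @export
lowpass_hs_enhance <- function(signal, cutoff_hz = 150, order = 10,
                               mode = c("zerophase", "single")) {
  signal <- as_hl_signal(signal)
  mode <- match.arg(mode)
  sos <- butter_lowpass(order, cutoff_hz, signal$rate)
  y <- if (mode == "zerophase") sos_filtfilt(sos, signal$samples)
       else sos_filter(sos, signal$samples)
  hl_signal(y, signal$rate)
}
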