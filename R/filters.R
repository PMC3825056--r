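# Butterworth low-pass design and application. Designed in second-order
# sections (cascaded biquads) because transfer-function polynomials of
# order 5-10 at the very low normalized cutoffs used here (15 Hz at 8 kHz,
# i.e. wn ~ 0.004) are numerically fragile. The biquad recursions run
# through stats::filter, i.e. at C speed.

#' Design a low-pass Butterworth filter as second-order sections
#'
#' Analog Butterworth prototype poles, frequency pre-warp, bilinear
#' transform, conjugate poles paired into biquads. DC gain is exactly 1.
#'
#' @param order Filter order (>= 1).
#' @param cutoff_hz Cutoff (-3 dB) frequency in Hz.
#' @param rate Sampling rate in Hz; `cutoff_hz` must be below `rate/2`.
#' @return An object of class `hl_sos`: a list with `sections` (each a
#'   list with numerator `b` and denominator `a`, `a[1] == 1`), plus the
#'   design parameters.
#' @export
butter_lowpass <- function(order, cutoff_hz, rate) {
  stopifnot(order >= 1, rate > 0)
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop("cutoff_hz must lie in (0, rate/2); got ", cutoff_hz,
         " at rate ", rate, call. = FALSE)
  n <- as.integer(order)
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # bilinear transform with fs = 2 (normalized), pre-warped cutoff
  fs2 <- 4                                 # 2 * fs
  wn <- cutoff_hz / (rate / 2)
  warped <- fs2 * tan(pi * wn / 2)
  p <- warped * p
  zp <- (fs2 + p) / (fs2 - p)              # digital poles
  # overall gain: H(s) = warped^n / prod(s - p); each bilinear factor
  # contributes 1/(fs2 - p_i) and a zero at z = -1
  gain <- Re(warped^n / prod(fs2 - p))

  sections <- list()
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (used[i]) next
    if (abs(Im(zp[i])) < 1e-12) {          # real pole (odd order)
      sections[[length(sections) + 1L]] <-
        list(b = c(1, 1, 0), a = c(1, -Re(zp[i]), 0))
      used[i] <- TRUE
    } else {
      j <- which(!used & abs(zp - Conj(zp[i])) < 1e-9)[1]
      sections[[length(sections) + 1L]] <-
        list(b = c(1, 2, 1),
             a = c(1, -2 * Re(zp[i]), Mod(zp[i])^2))
      used[c(i, j)] <- TRUE
    }
  }
  sections[[1]]$b <- sections[[1]]$b * gain
  structure(list(sections = sections, order = n, cutoff_hz = cutoff_hz,
                 rate = rate),
            class = "hl_sos")
}

# One causal pass of a single biquad via stats::filter. The section is
# seeded with its steady state for a constant input equal to the first
# sample, so a constant-start signal produces no startup transient
# (the role scipy's lfilter_zi plays inside filtfilt).
biquad_filter <- function(x, b, a) {
  n <- length(x)
  xp <- c(x[1], x[1], x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[3:(n + 2)]
  if (abs(a[2]) < .Machine$double.eps && abs(a[3]) < .Machine$double.eps)
    return(v)
  y0 <- x[1] * sum(b) / (1 + a[2] + a[3])
  as.numeric(stats::filter(v, -a[2:3], method = "recursive",
                           init = c(y0, y0)))
}

#' Apply a filter causally (single forward pass)
#'
#' @param sos An `hl_sos` from [butter_lowpass()].
#' @param x Numeric vector.
#' @return Filtered vector, same length.
#' @export
sos_filter <- function(sos, x) {
  for (s in sos$sections) x <- biquad_filter(x, s$b, s$a)
  x
}

#' Apply a filter forward-backward (zero phase)
#'
#' Squares the magnitude response (-6 dB at the design cutoff) and cancels
#' the phase, so features are not delayed -- the property boundary
#' estimation relies on. Startup transients are suppressed by odd
#' (point-reflected) extension of length `3 * order` at both ends before
#' filtering, mirroring the common filtfilt contract.
#'
#' @inheritParams sos_filter
#' @return Filtered vector, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  pad <- min(3L * sos$order, n - 1L)
  if (pad > 0) {
    front <- 2 * x[1] - x[seq(pad + 1, 2)]
    back  <- 2 * x[n] - x[seq(n - 1, n - pad)]
    ext <- c(front, x, back)
  } else ext <- x
  y <- sos_filter(sos, ext)
  y <- rev(sos_filter(sos, rev(y)))
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

#' Magnitude/phase response of a designed filter
#'
#' Evaluates `H(e^{i 2 pi f / rate})` directly from the section
#' coefficients; used by the test suite as the independent oracle for
#' time-domain attenuation checks.
#'
#' @param sos An `hl_sos`.
#' @param freq_hz Frequencies (Hz) at which to evaluate.
#' @param zerophase If `TRUE`, return the response of the
#'   forward-backward application, `|H|^2` (zero phase).
#' @return Complex response vector.
#' @export
sos_response <- function(sos, freq_hz, zerophase = FALSE) {
  w <- 2 * pi * freq_hz / sos$rate
  z1 <- exp(-1i * w)
  h <- rep(1 + 0i, length(w))
  for (s in sos$sections) {
    num <- s$b[1] + s$b[2] * z1 + s$b[3] * z1^2
    den <- s$a[1] + s$a[2] * z1 + s$a[3] * z1^2
    h <- h * num / den
  }
  if (zerophase) h <- Mod(h)^2
  h
}
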