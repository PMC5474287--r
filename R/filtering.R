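#' Butterworth low-pass design as second-order sections
#'
#' Designs an even-order digital Butterworth low-pass by pairing the analog
#' prototype poles into biquads and bilinear-transforming each section with
#' frequency prewarping. High-order Butterworth filters are numerically
#' unusable as a single polynomial; the cascaded-biquad form is exact at any
#' order.
#'
#' @param order filter order (even, >= 2).
#' @param cutoff -3 dB cutoff frequency (Hz), `0 < cutoff < fs/2`.
#' @param fs sampling rate (Hz).
#' @return Matrix with `order/2` rows and columns `b0,b1,b2,a1,a2`
#'   (denominator normalized, `a0 = 1`).
#' @keywords internal
butter_lowpass_sos <- function(order, cutoff, fs) {
  if (order < 2L || order %% 2L != 0L)
    stop("'order' must be an even integer >= 2", call. = FALSE)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("'cutoff' must lie strictly between 0 and Nyquist (", fs / 2,
         " Hz)", call. = FALSE)
  K <- 2 * fs
  wa <- K * tan(pi * cutoff / fs)        # prewarped analog cutoff (rad/s)
  k <- seq_len(order %/% 2L)
  sphi <- sin(pi * (2 * k - 1) / (2 * order))  # -Re of prototype pole pair
  a0 <- K^2 + 2 * sphi * wa * K + wa^2
  sos <- cbind(b0 = wa^2 / a0, b1 = 2 * wa^2 / a0, b2 = wa^2 / a0,
               a1 = (2 * wa^2 - 2 * K^2) / a0,
               a2 = (K^2 - 2 * sphi * wa * K + wa^2) / a0)
  sos
}

# One biquad pass, vectorised: MA part by shifted sums, AR part through the
# compiled recursion in stats::filter. Initial conditions are the steady
# state for a constant input equal to the first sample, so a constant signal
# passes through with no transient at all.
biquad_pass <- function(x, s) {
  n <- length(x)
  x0 <- x[1L]
  xm1 <- c(x0, x[-n])
  xm2 <- c(x0, x0, x[seq_len(max(n - 2L, 0L))])[seq_len(n)]
  u <- s[["b0"]] * x + s[["b1"]] * xm1 + s[["b2"]] * xm2
  dc <- (s[["b0"]] + s[["b1"]] + s[["b2"]]) / (1 + s[["a1"]] + s[["a2"]])
  y0 <- x0 * dc
  as.numeric(stats::filter(u, filter = c(-s[["a1"]], -s[["a2"]]),
                           method = "recursive", init = c(y0, y0)))
}

sos_forward <- function(x, sos) {
  for (i in seq_len(nrow(sos))) x <- biquad_pass(x, sos[i, ])
  x
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an even-order Butterworth low-pass forward and backward
#' (second-order-section realization), so the phase response is exactly zero
#' and the effective magnitude is the squared single-pass response. This is
#' the offline acquisition filter of the measurement chain: the default
#' matches a 20th-order, 150 Hz cutoff applied to 1024 Hz force recordings.
#' Odd-reflection edge padding suppresses startup transients; output length
#' equals input length.
#'
#' @param signal a `force_signal`.
#' @param cutoff cutoff frequency in Hz (default 150); must be below Nyquist.
#' @param order filter order (even; default 20).
#' @return The filtered `force_signal`.
#' @export
lowpass_zero_phase <- function(signal, cutoff = 150, order = 20L) {
  stopifnot(inherits(signal, "force_signal"))
  sos <- butter_lowpass_sos(order, cutoff, signal$fs)
  x <- signal$samples
  n <- length(x)
  pad <- min(n - 1L, 6L * order)
  if (pad > 0L) {
    head_ref <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
    tail_ref <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xp <- c(head_ref, x, tail_ref)
  } else {
    xp <- x
  }
  y <- sos_forward(xp, sos)
  y <- rev(sos_forward(rev(y), sos))
  if (pad > 0L) y <- y[(pad + 1L):(pad + n)]
  force_signal(y, fs = signal$fs, label = signal$label)
}

#' Squared Butterworth magnitude response
#'
#' Magnitude of the zero-phase (forward-backward) Butterworth filter at given
#' frequencies — the square of the single-pass digital magnitude. Useful for
#' predicting attenuation analytically.
#'
#' @param f frequencies (Hz).
#' @inheritParams lowpass_zero_phase
#' @param fs sampling rate (Hz).
#' @return Numeric vector of magnitudes.
#' @export
zero_phase_magnitude <- function(f, cutoff = 150, order = 20L, fs = 1024) {
  sos <- butter_lowpass_sos(order, cutoff, fs)
  z <- exp(-2i * pi * f / fs)
  H <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    s <- sos[i, ]
    H <- H * (s[["b0"]] + s[["b1"]] * z + s[["b2"]] * z^2) /
      (1 + s[["a1"]] * z + s[["a2"]] * z^2)
  }
  Mod(H)^2
}
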