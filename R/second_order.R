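#' Second-order structural model parameters
#'
#' Natural frequency and damping ratio of the benchmark model of an
#' indirect-measurement force treadmill (IMFT): the treadmill frame treated as
#' a mass on a stiff mount, a single damped second-order mode.
#'
#' @param fn natural frequency (Hz, > 0).
#' @param xi damping ratio (dimensionless, >= 0).
#' @param gain static gain (dimensionless, default 1).
#' @return An object of class `second_order_params`.
#' @export
second_order_params <- function(fn, xi, gain = 1) {
  if (!is.numeric(fn) || fn <= 0) stop("'fn' must be > 0 Hz", call. = FALSE)
  if (!is.numeric(xi) || xi < 0) stop("'xi' must be >= 0", call. = FALSE)
  structure(list(fn = fn, xi = xi, gain = gain),
            class = "second_order_params")
}

#' Amplitude response of a standard second-order system
#'
#' `|H(u)| = 1 / sqrt((1 - u^2)^2 + 4 xi^2 u^2)` with dimensionless frequency
#' `u = f / fn`. At `u << 1` this tends to 1, which is why a rigid (high-`fn`)
#' treadmill transmits the GRF nearly undistorted; near `u = 1` it resonates.
#'
#' @param u dimensionless frequency `f / fn` (vectorized).
#' @param xi damping ratio (recycled against `u`).
#' @return Magnitudes (dimensionless).
#' @examples
#' amplitude_response(12.75 / 45, 0)   # ~1.087: 8.7% error at a 45 Hz mount
#' amplitude_response(12.75 / 160, 0)  # ~1.006
#' @export
amplitude_response <- function(u, xi) {
  d2 <- (1 - u^2)^2 + 4 * xi^2 * u^2
  if (any(d2 == 0))
    stop("undamped resonance: u = 1 with xi = 0 is a pole (infinite response)",
         call. = FALSE)
  1 / sqrt(d2)
}

#' Phase response of a standard second-order system
#'
#' The continuous branch of `-atan(2 xi u / (1 - u^2))`: phase runs from 0 at
#' DC through `-pi/2` at resonance towards `-pi` at high frequency, matching
#' the physical lag of a second-order system. (The principal-value arctangent
#' flips sign above `u = 1`; this function unwraps it.)
#'
#' @inheritParams amplitude_response
#' @return Phase in radians, in `[-pi, 0]`.
#' @export
phase_response <- function(u, xi) {
  -atan2(2 * xi * u, 1 - u^2)
}

#' Complex second-order frequency response
#'
#' `H(u) = gain / (1 - u^2 + 2i xi u)`; its modulus and argument are
#' [amplitude_response()] and [phase_response()].
#'
#' @inheritParams amplitude_response
#' @param gain static gain.
#' @return Complex response values.
#' @export
second_order_frf <- function(u, xi, gain = 1) {
  den <- complex(real = 1 - u^2, imaginary = 2 * xi * u)
  if (any(den == 0))
    stop("undamped resonance: u = 1 with xi = 0 is a pole (infinite response)",
         call. = FALSE)
  gain / den
}

#' Natural frequency from stiffness and mass
#'
#' `fn = sqrt(k / m) / (2 pi)`: the free-oscillation frequency of the
#' treadmill structure. Stiffening the mount or lightening the frame raises
#' `fn` — the conventional (hardware) route to low-distortion force
#' treadmills.
#'
#' @param stiffness structural stiffness (N/m, > 0).
#' @param mass structural mass (kg, > 0).
#' @return Natural frequency in Hz.
#' @export
natural_frequency <- function(stiffness, mass) {
  if (any(stiffness <= 0) || any(mass <= 0))
    stop("'stiffness' and 'mass' must be positive", call. = FALSE)
  sqrt(stiffness / mass) / (2 * pi)
}

#' Distortionless-transmission parameters
#'
#' A distortionless transmission outputs a scaled, delayed copy of its input:
#' `y(t) = k x(t - td)`. In the frequency domain that is a constant amplitude
#' response `k` and a phase linear in frequency, `-2 pi f td`.
#'
#' @param k proportionality constant (dimensionless).
#' @param td time delay (s, >= 0).
#' @return An object of class `distortionless_params`.
#' @export
distortionless_params <- function(k = 1, td = 0) {
  if (td < 0) stop("'td' must be >= 0", call. = FALSE)
  structure(list(k = k, td = td), class = "distortionless_params")
}

#' Frequency response of a distortionless transmission
#'
#' `H(f) = k exp(-2i pi f td)` evaluated on a spectrum's grid (or on a bare
#' frequency vector).
#'
#' @param params a `distortionless_params`.
#' @param grid a `force_spectrum` template or numeric frequency vector (Hz).
#' @return A `force_spectrum` on the template's grid, or a complex vector if
#'   `grid` is numeric.
#' @export
distortionless_transfer <- function(params, grid) {
  stopifnot(inherits(params, "distortionless_params"))
  if (inherits(grid, "force_spectrum")) {
    f <- spectrum_freqs(grid)
    force_spectrum(params$k * exp(-2i * pi * f * params$td),
                   fs = grid$fs, nfft = grid$nfft)
  } else {
    params$k * exp(-2i * pi * as.numeric(grid) * params$td)
  }
}

#' Pass a force signal through a second-order system
#'
#' Spectral application of the full complex response
#' `H = gain / (1 - u^2 + 2i xi u)` at every transform bin — the benchmark for
#' what an IMFT with that mount would report as GRF. The transform is circular
#' at `nfft =` signal length by default (exact for periodic records); pass a
#' larger `nfft` to zero-pad.
#'
#' @param signal input `force_signal` (the true GRF).
#' @param params a `second_order_params`.
#' @param nfft optional transform length.
#' @return The transmitted `force_signal`, same length as the input.
#' @export
apply_second_order <- function(signal, params, nfft = NULL) {
  stopifnot(inherits(signal, "force_signal"),
            inherits(params, "second_order_params"))
  if (params$fn >= signal$fs / 2)
    warning("natural frequency ", params$fn, " Hz is at or above Nyquist (",
            signal$fs / 2, " Hz); the resonance is not representable")
  apply_frf(signal,
            function(f) second_order_frf(f / params$fn, params$xi,
                                         params$gain),
            nfft = nfft, label = signal$label)
}

#' Distortion sweep of the second-order IMFT benchmark
#'
#' For each combination of natural frequency and damping ratio, passes the
#' GRF through the second-order model and scores the output against the input
#' with the THD energy-ratio metric. Reproduces the classic design trade-off:
#' distortion falls as the mount's natural frequency rises above the GRF
#' bandwidth, and damping tames the resonant pickup.
#'
#' @param grf reference GRF `force_signal`.
#' @param fn_grid natural frequencies to evaluate (Hz).
#' @param xi_list damping ratios to evaluate.
#' @return `data.frame` with columns `fn_hz`, `xi`, `thd_percent`, sorted by
#'   `fn_hz` then `xi`.
#' @export
thd_sweep <- function(grf, fn_grid, xi_list) {
  stopifnot(inherits(grf, "force_signal"), length(grf$samples) > 0)
  grid <- expand.grid(xi = xi_list, fn_hz = sort(fn_grid))
  res <- mapply(function(fn, xi) {
    y <- apply_second_order(grf, second_order_params(fn, xi))
    100 * thd(y, grf)$thd
  }, grid$fn_hz, grid$xi)
  data.frame(fn_hz = grid$fn_hz, xi = grid$xi, thd_percent = res)
}
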