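#' Options for regularized transfer-function inversion
#'
#' The raw inverse `1/H` amplifies noise without bound wherever the structure
#' antiresonates, so the inversion is Tikhonov-regularized and band-limited.
#'
#' @param reg_eps regularization level as a fraction of peak `|H|`
#'   (`0 <= reg_eps < 1`); default 1e-2. Zero gives the exact inverse.
#' @param f_max inversion band limit in Hz; default 150, matching the
#'   acquisition filter cutoff — above it the measured signal carries no
#'   credible content.
#' @param outside_band `"zero"` (default) or `"passthrough"`: what the
#'   inverse does above `f_max`.
#' @param dc_gain `"unity"` (default: the static component of the measurement
#'   is carried through compensation unchanged, so body weight survives) or
#'   `"identified"` (rescale it by the identified static gain).
#' @return An object of class `inversion_options`.
#' @export
inversion_options <- function(reg_eps = 1e-2, f_max = 150,
                              outside_band = c("zero", "passthrough"),
                              dc_gain = c("unity", "identified")) {
  if (reg_eps < 0 || reg_eps >= 1)
    stop("'reg_eps' must lie in [0, 1)", call. = FALSE)
  if (f_max <= 0) stop("'f_max' must be > 0 Hz", call. = FALSE)
  structure(list(reg_eps = reg_eps, f_max = f_max,
                 outside_band = match.arg(outside_band),
                 dc_gain = match.arg(dc_gain)),
            class = "inversion_options")
}

#' Regularized inverse of a transfer-function estimate
#'
#' Per-bin Tikhonov (water-level) inverse
#' `conj(H) / (|H|^2 + (reg_eps * max|H|)^2)` for `f <= f_max`; bins above
#' `f_max` are zeroed or passed through per the option, and masked
#' (unexcited) bins are always zeroed. The inverse magnitude is thus bounded
#' by `1 / (2 reg_eps max|H|)` however deep the antiresonance.
#'
#' @param tf a `tf_estimate`.
#' @param opts an `inversion_options`.
#' @return A `force_spectrum` holding the inverse response on the estimate's
#'   grid.
#' @export
invert_transfer <- function(tf, opts = inversion_options()) {
  stopifnot(inherits(tf, "tf_estimate"), inherits(opts, "inversion_options"))
  if (all(tf$masked))
    stop("transfer function is entirely masked; nothing to invert",
         call. = FALSE)
  H <- tf$spectrum$values
  H[tf$masked] <- 0
  peak <- max(Mod(H))
  lam2 <- (opts$reg_eps * peak)^2
  Hinv <- rep(0 + 0i, length(H))
  ok <- !tf$masked & (Mod(H)^2 + lam2) > 0
  Hinv[ok] <- Conj(H[ok]) / (Mod(H[ok])^2 + lam2)
  f <- spectrum_freqs(tf$spectrum)
  outside <- f > opts$f_max
  Hinv[outside] <- switch(opts$outside_band, zero = 0 + 0i,
                          passthrough = 1 + 0i)
  Hinv[outside & tf$masked] <- 0 + 0i
  force_spectrum(Hinv, fs = tf$spectrum$fs, nfft = tf$spectrum$nfft)
}

# Linear interpolation of a tf_estimate onto a new transform grid; real and
# imaginary parts are interpolated from unmasked bins only, and a target bin
# is masked whenever a bracketing source bin was masked.
resample_tf <- function(tf, fs, nfft) {
  src_f <- spectrum_freqs(tf$spectrum)
  tgt_f <- (fs / nfft) * (0:(nfft %/% 2L))
  if (tf$spectrum$fs == fs && tf$spectrum$nfft == nfft) return(tf)
  ok <- !tf$masked
  if (sum(ok) < 2L)
    stop("fewer than two unmasked bins; cannot resample the transfer function",
         call. = FALSE)
  re <- stats::approx(src_f[ok], Re(tf$spectrum$values[ok]), tgt_f,
                      rule = 2)$y
  im <- stats::approx(src_f[ok], Im(tf$spectrum$values[ok]), tgt_f,
                      rule = 2)$y
  coh <- stats::approx(src_f, tf$coherence, tgt_f, rule = 2)$y
  msk <- stats::approx(src_f, as.numeric(tf$masked), tgt_f, rule = 2)$y > 0
  # outside the identified band: masked
  msk[tgt_f > max(src_f[ok]) | tgt_f < min(src_f[ok])] <- TRUE
  tf_estimate(force_spectrum(complex(real = re, imaginary = im),
                             fs = fs, nfft = nfft),
              coherence = coh, masked = msk, method = tf$method,
              n_trials = tf$n_trials)
}

#' Reconstruct the track-surface GRF from the load-cell measurement
#'
#' The inverse-dynamics compensation: `x_c(t)` is the inverse transform of
#' `Hinv(f) * Y(f)`, where `Hinv` is the regularized inverse of the
#' identified transmission transfer function. The static component is handled
#' separately: the measurement mean is removed before inversion (impact-based
#' estimates of the DC response are unreliable) and added back per the
#' `dc_gain` option, so the body-weight baseline survives compensation.
#'
#' The transform is circular at `nfft =` signal length by default — exact for
#' periodic (steady-gait) records and for transients contained in the record;
#' pass a larger even `nfft` in `nfft` to zero-pad instead. If the estimate's
#' grid differs from the measurement's transform grid, the transfer function
#' is linearly interpolated (real and imaginary parts) onto it.
#'
#' @param y measured (uncompensated) `force_signal`.
#' @param tf identified `tf_estimate`; its originating sampling rate must
#'   equal `y$fs`.
#' @param opts an `inversion_options`.
#' @param nfft optional even transform length `>= length(y)`.
#' @return The compensated `force_signal` `x_c`, same length as `y`.
#' @export
compensate <- function(y, tf, opts = inversion_options(), nfft = NULL) {
  stopifnot(inherits(y, "force_signal"), inherits(tf, "tf_estimate"),
            inherits(opts, "inversion_options"))
  if (abs(tf$spectrum$fs - y$fs) > 1e-9 * y$fs)
    stop("transfer function was identified at ", tf$spectrum$fs,
         " Hz but the measurement is sampled at ", y$fs, " Hz", call. = FALSE)
  n <- length(y$samples)
  if (is.null(nfft)) nfft <- default_nfft(n)
  nfft <- as.integer(nfft)
  tfg <- resample_tf(tf, fs = y$fs, nfft = nfft)
  Hinv <- invert_transfer(tfg, opts)
  m <- mean(y$samples)
  dyn <- force_signal(y$samples - m, fs = y$fs, label = y$label)
  xc <- apply_frf(dyn, Hinv$values, nfft = nfft, label = y$label)
  g0 <- 1
  if (opts$dc_gain == "identified" && !tfg$masked[1L]) {
    h0 <- Re(tfg$spectrum$values[1L])
    if (is.finite(h0) && abs(h0) > 1e-6) g0 <- h0
  }
  force_signal(xc$samples + m / g0, fs = y$fs,
               label = paste0(y$label, "_compensated"))
}
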