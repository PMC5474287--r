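#' One-sided complex spectrum
#'
#' Complex amplitudes of a real signal on the uniform one-sided frequency grid
#' `0, df, 2 df, ..., fs/2` with `df = fs / nfft`. The normalization convention
#' is fixed package-wide: the forward transform is the unscaled DFT and the
#' inverse divides by `nfft`, so `inverse_spectrum(forward_spectrum(x))`
#' reproduces `x` exactly.
#'
#' @param values complex vector of length `nfft / 2 + 1`.
#' @param fs originating sampling rate (Hz).
#' @param nfft transform length (even).
#' @return An object of class `force_spectrum`.
#' @export
force_spectrum <- function(values, fs, nfft) {
  nfft <- as.integer(nfft)
  if (nfft < 2L || nfft %% 2L != 0L)
    stop("'nfft' must be an even integer >= 2", call. = FALSE)
  if (length(values) != nfft %/% 2L + 1L)
    stop("one-sided spectrum for nfft = ", nfft, " must have ",
         nfft %/% 2L + 1L, " bins, got ", length(values), call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be positive", call. = FALSE)
  structure(list(values = as.complex(values), fs = as.numeric(fs),
                 nfft = nfft, df = fs / nfft),
            class = "force_spectrum")
}

#' @export
print.force_spectrum <- function(x, ...) {
  cat(sprintf("<force_spectrum> %d bins, df = %.6g Hz, 0..%.6g Hz (nfft %d @ %g Hz)\n",
              length(x$values), x$df, x$fs / 2, x$nfft, x$fs))
  invisible(x)
}

#' Frequency grid of a one-sided spectrum
#' @param spec a `force_spectrum`.
#' @return Numeric vector `0, df, ..., fs/2`.
#' @export
spectrum_freqs <- function(spec) {
  stopifnot(inherits(spec, "force_spectrum"))
  spec$df * (seq_along(spec$values) - 1L)
}

next_pow2 <- function(n) as.integer(2^ceiling(log2(max(n, 2L))))

# default transform length: the signal length itself (even; +1 zero pad if
# odd) so that the forward/inverse pair is an exact circular bijection.
default_nfft <- function(n) as.integer(n + n %% 2L)

#' Forward Fourier transform of a force signal
#'
#' Unscaled DFT, one-sided. When `nfft` exceeds the signal length the signal
#' is zero-padded. Default `nfft` is the signal length (rounded up to even):
#' the transform is then an exact circular bijection, which the compensation
#' pipeline relies on.
#'
#' @param signal a `force_signal`.
#' @param nfft optional even transform length `>=` signal length.
#' @return A `force_spectrum`.
#' @export
forward_spectrum <- function(signal, nfft = NULL) {
  stopifnot(inherits(signal, "force_signal"))
  n <- length(signal$samples)
  if (is.null(nfft)) nfft <- default_nfft(n)
  nfft <- as.integer(nfft)
  if (nfft < n)
    stop("'nfft' (", nfft, ") must be >= signal length (", n, ")",
         call. = FALSE)
  if (nfft %% 2L != 0L)
    stop("'nfft' must be even so the grid ends exactly at Nyquist",
         call. = FALSE)
  x <- c(signal$samples, numeric(nfft - n))
  X <- stats::fft(x)
  force_spectrum(X[seq_len(nfft %/% 2L + 1L)], fs = signal$fs, nfft = nfft)
}

#' Inverse Fourier transform back to a force signal
#'
#' Rebuilds the conjugate-symmetric full spectrum from the one-sided values,
#' inverts (dividing by `nfft`), and returns the first `out_length` samples.
#' The DC and Nyquist bins of a real signal's spectrum are real; a significant
#' imaginary part there means the spectrum is not conjugate-symmetric
#' (corrupt input) and is an error. Residual imaginary parts of the inverse
#' below 1e-9 relative are discarded.
#'
#' @param spec a `force_spectrum`.
#' @param out_length number of samples to return (`<= nfft`); default `nfft`.
#' @param label channel name for the result.
#' @return A `force_signal` at the spectrum's originating sampling rate.
#' @export
inverse_spectrum <- function(spec, out_length = NULL, label = "inverse") {
  stopifnot(inherits(spec, "force_spectrum"))
  nfft <- spec$nfft
  if (is.null(out_length)) out_length <- nfft
  if (out_length > nfft || out_length < 1L)
    stop("'out_length' must be in 1..nfft", call. = FALSE)
  v <- spec$values
  n2 <- nfft %/% 2L
  scale <- max(Mod(v), .Machine$double.xmin)
  if (abs(Im(v[1L])) > 1e-9 * scale || abs(Im(v[n2 + 1L])) > 1e-9 * scale)
    stop("spectrum is not conjugate-symmetric: DC or Nyquist bin has a ",
         "significant imaginary part (corrupt input)", call. = FALSE)
  full <- c(complex(real = Re(v[1L])), v[2:n2],
            complex(real = Re(v[n2 + 1L])), Conj(v[n2:2]))
  x <- stats::fft(full, inverse = TRUE) / nfft
  resid <- max(abs(Im(x)))
  if (resid > 1e-9 * max(max(abs(Re(x))), .Machine$double.xmin))
    stop("inverse transform left a large imaginary residue (",
         signif(resid, 3), "); spectrum is not conjugate-symmetric",
         call. = FALSE)
  force_signal(Re(x)[seq_len(out_length)], fs = spec$fs, label = label)
}

#' Apply a frequency response to a signal
#'
#' Multiplies the signal's one-sided spectrum by a complex frequency response
#' and inverts. The response may be a function of frequency (Hz) returning
#' complex values, or a complex vector already on the transform grid. The
#' Nyquist-bin response is forced real so the output stays real (the response
#' of any real system is real there).
#'
#' @param signal a `force_signal`.
#' @param frf function(f_hz) -> complex, or complex vector of length
#'   `nfft/2 + 1`.
#' @param nfft optional transform length (default: signal length, even).
#' @param label output channel name.
#' @return A `force_signal` of the same length as the input.
#' @export
apply_frf <- function(signal, frf, nfft = NULL, label = NULL) {
  stopifnot(inherits(signal, "force_signal"))
  spec <- forward_spectrum(signal, nfft = nfft)
  f <- spectrum_freqs(spec)
  H <- if (is.function(frf)) frf(f) else as.complex(frf)
  if (length(H) != length(spec$values))
    stop("frequency response has ", length(H), " bins; transform grid has ",
         length(spec$values), call. = FALSE)
  nb <- length(H)
  H[1L] <- complex(real = Re(H[1L]))
  H[nb] <- complex(real = Re(H[nb]))
  out <- force_spectrum(spec$values * H, fs = spec$fs, nfft = spec$nfft)
  inverse_spectrum(out, out_length = length(signal$samples),
                   label = label %||% signal$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
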