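#' Total harmonic distortion of a GRF estimate
#'
#' Waveform-fidelity metric: the ratio of the energy of the estimation-error
#' signal to the energy of the reference signal over the record,
#' `THD = sum((xhat - x)^2) / sum(x^2)` (the sample-interval factors cancel).
#' Note this is an energy ratio over the whole waveform, not the
#' audio-engineering harmonic-by-harmonic THD. Signals are compared at
#' identical time indices — no lag search — because the compensation path is
#' zero-phase.
#'
#' The canonical number is the energy ratio itself; the amplitude-domain
#' square-root convention is also carried in the result for comparability.
#'
#' @param estimate estimated GRF (`force_signal`).
#' @param reference true GRF (`force_signal`), same fs and length, not
#'   identically zero.
#' @return An object of class `thd_result` with fields `thd` (energy ratio,
#'   dimensionless), `thd_sqrt` (its square root), `error_energy` and
#'   `signal_energy` (N^2 s), `duration` (s).
#' @examples
#' x <- force_signal(700 + 100 * sin(2 * pi * 2 * (0:2047) / 1024), 1024)
#' xhat <- force_signal(1.1 * x$samples, 1024)
#' thd(xhat, x)   # 1% — a uniform 10% amplitude error costs 1% in energy
#' @export
thd <- function(estimate, reference) {
  stopifnot(inherits(estimate, "force_signal"),
            inherits(reference, "force_signal"))
  if (estimate$fs != reference$fs)
    stop("estimate and reference disagree on sampling rate", call. = FALSE)
  if (length(estimate$samples) != length(reference$samples))
    stop("estimate and reference disagree on length", call. = FALSE)
  dt <- 1 / reference$fs
  e2 <- sum((estimate$samples - reference$samples)^2) * dt
  s2 <- sum(reference$samples^2) * dt
  if (s2 == 0)
    stop("reference signal has zero energy; THD is undefined", call. = FALSE)
  structure(list(thd = e2 / s2, thd_sqrt = sqrt(e2 / s2),
                 error_energy = e2, signal_energy = s2,
                 duration = duration(reference)),
            class = "thd_result")
}

#' @export
print.thd_result <- function(x, ...) {
  cat(sprintf("THD = %.4g%% (energy ratio; sqrt convention %.4g%%)\n",
              100 * x$thd, 100 * x$thd_sqrt))
  cat(sprintf("  error energy %.6g N^2 s / signal energy %.6g N^2 s over %.4g s\n",
              x$error_energy, x$signal_energy, x$duration))
  invisible(x)
}

#' Energy bandwidth of a signal
#'
#' The smallest grid frequency B such that the one-sided spectral energy over
#' `[0, B]` reaches the given fraction of the total — by default the 98%
#' bandwidth. The DC bin is included in the total by default (the body-weight
#' baseline of a walk-on-the-spot record carries real energy); set
#' `include_dc = FALSE` to measure the fluctuating component only.
#'
#' @param signal a `force_signal`.
#' @param fraction energy fraction in (0, 1); default 0.98.
#' @param include_dc include the DC bin in total and cumulative energy.
#' @param nfft optional transform length (default: signal length, even).
#' @return Bandwidth in Hz.
#' @export
bandwidth_98 <- function(signal, fraction = 0.98, include_dc = TRUE,
                         nfft = NULL) {
  stopifnot(inherits(signal, "force_signal"))
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly between 0 and 1", call. = FALSE)
  spec <- forward_spectrum(signal, nfft = nfft)
  nb <- length(spec$values)
  w <- c(1, rep(2, nb - 2L), 1)          # fold the negative-frequency half
  e <- w * Mod(spec$values)^2
  if (!include_dc) e[1L] <- 0
  total <- sum(e)
  if (total == 0) return(0)
  k <- which(cumsum(e) >= fraction * total)[1L]
  spec$df * (k - 1L)
}

#' Association between reconstruction distortion and signal bandwidth
#'
#' Pearson product-moment correlation (with its two-sided t-test p-value)
#' between per-record THD values and 98% bandwidths — wider-band GRF pushes
#' more energy into the frequency range where identification is noisier, so a
#' positive association is expected.
#'
#' @param thds numeric vector of THD values.
#' @param bandwidths numeric vector of bandwidths (Hz), same length (>= 3).
#' @return List with `r` (correlation coefficient) and `p_value`.
#' @export
bandwidth_thd_association <- function(thds, bandwidths) {
  if (length(thds) != length(bandwidths) || length(thds) < 3L)
    stop("need equal-length vectors of at least 3 pairs", call. = FALSE)
  if (stats::sd(thds) == 0 || stats::sd(bandwidths) == 0)
    stop("correlation is undefined for a constant vector", call. = FALSE)
  ct <- stats::cor.test(bandwidths, thds, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
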