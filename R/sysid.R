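#' Paired impact trial
#'
#' One hammer-strike recording: the reference force `x` measured by the force
#' platform on the track surface and the transmitted force `y` summed over the
#' under-frame load cells. Identification ratios the two spectra.
#'
#' @param x reference `force_signal`.
#' @param y transmitted `force_signal`, same fs and length.
#' @return An object of class `impact_trial`.
#' @export
impact_trial <- function(x, y) {
  stopifnot(inherits(x, "force_signal"), inherits(y, "force_signal"))
  if (x$fs != y$fs)
    stop("x and y disagree on sampling rate", call. = FALSE)
  if (length(x$samples) != length(y$samples))
    stop("x and y disagree on length", call. = FALSE)
  structure(list(x = x, y = y), class = "impact_trial")
}

#' Transfer-function estimate
#'
#' Complex frequency response with a per-bin coherence and an excitation mask.
#' Bins where the excitation spectrum falls below the masking threshold are
#' flagged rather than divided — the estimate never silently extrapolates into
#' unexcited bands.
#'
#' @param spectrum `force_spectrum` of complex response values.
#' @param coherence per-bin coherence in `[0, 1]` (1 for a single-trial raw
#'   ratio, where it is undefined).
#' @param masked logical per-bin excitation mask (TRUE = unexcited/invalid).
#' @param method `"raw-ratio"` or `"h1-averaged"`.
#' @param n_trials number of trials averaged.
#' @return An object of class `tf_estimate`.
#' @export
tf_estimate <- function(spectrum, coherence, masked, method, n_trials) {
  stopifnot(inherits(spectrum, "force_spectrum"))
  nb <- length(spectrum$values)
  coherence <- rep_len(as.numeric(coherence), nb)
  masked <- rep_len(as.logical(masked), nb)
  ok <- is.finite(coherence[!masked])
  if (any(coherence[!masked][ok] < -1e-12 | coherence[!masked][ok] > 1 + 1e-9))
    stop("coherence must lie in [0, 1]", call. = FALSE)
  structure(list(spectrum = spectrum,
                 coherence = pmin(pmax(coherence, 0), 1),
                 masked = masked,
                 method = match.arg(method, c("raw-ratio", "h1-averaged")),
                 n_trials = as.integer(n_trials)),
            class = "tf_estimate")
}

#' @export
print.tf_estimate <- function(x, ...) {
  cat(sprintf("<tf_estimate> %s over %d trial(s); %d bins (df %.4g Hz), %.1f%% masked\n",
              x$method, x$n_trials, length(x$spectrum$values),
              x$spectrum$df, 100 * mean(x$masked)))
  if (x$method == "h1-averaged")
    cat(sprintf("  median coherence (unmasked): %.3f\n",
                stats::median(x$coherence[!x$masked])))
  invisible(x)
}

#' Segment hammer strikes in a recording
#'
#' Finds contiguous runs where `|signal|` exceeds the threshold, extends each
#' by `pre_window` before its first crossing and `post_window` after its last,
#' merges overlapping extents and clips to the record. No crossing yields an
#' empty result, not an error.
#'
#' @param signal a `force_signal`.
#' @param threshold detection threshold in N (> 0).
#' @param pre_window seconds kept before each first crossing.
#' @param post_window seconds kept after each last crossing.
#' @return Integer matrix with columns `start`, `end` (1-based sample
#'   indices), zero rows if nothing crosses.
#' @export
detect_impacts <- function(signal, threshold, pre_window = 0.05,
                           post_window = 0.5) {
  stopifnot(inherits(signal, "force_signal"))
  if (threshold <= 0) stop("'threshold' must be > 0 N", call. = FALSE)
  if (pre_window < 0 || post_window < 0)
    stop("windows must be >= 0 s", call. = FALSE)
  n <- length(signal$samples)
  above <- abs(signal$samples) > threshold
  empty <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (!any(above)) return(empty)
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  pre_n <- round(pre_window * signal$fs)
  post_n <- round(post_window * signal$fs)
  starts <- pmax(starts - pre_n, 1L)
  ends <- pmin(ends + post_n, n)
  # merge overlapping / touching extents
  keep_s <- starts[1L]; out <- NULL; cur_e <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, ends[i])
    } else {
      out <- rbind(out, c(keep_s, cur_e))
      keep_s <- starts[i]; cur_e <- ends[i]
    }
  }
  out <- rbind(out, c(keep_s, cur_e))
  colnames(out) <- c("start", "end")
  storage.mode(out) <- "integer"
  out
}

# Subtract the pre-trigger mean from both channels of a trial: the ratio
# concerns the dynamic component, and load cells carry a static preload.
# Onset is the first sample where |x| exceeds onset_frac of its peak.
baseline_correct_trial <- function(trial, onset_frac = 0.05) {
  ax <- abs(trial$x$samples)
  onset <- which(ax > onset_frac * max(ax))[1L]
  idx <- if (!is.na(onset) && onset > 8L) seq_len(onset - 1L)
         else seq_along(ax)
  x <- trial$x$samples - mean(trial$x$samples[idx])
  y <- trial$y$samples - mean(trial$y$samples[idx])
  list(x = x, y = y)
}

# optional exponential window for noisy decaying tails
trial_window <- function(n, window) {
  switch(window,
         rectangular = rep(1, n),
         exponential = exp(-4 * (seq_len(n) - 1L) / (n - 1L)),
         stop("unknown window '", window, "'", call. = FALSE))
}

#' Single-trial transfer-function estimate (raw spectral ratio)
#'
#' The direct definition `H(f) = Y(f) / X(f)` computed from one strike. Bins
#' where the excitation magnitude `|X|` falls below `eps_id` times its peak
#' are masked rather than divided — hammer spectra roll off, and dividing by
#' near-zero bins amplifies noise without bound.
#'
#' @param trial an `impact_trial`.
#' @param nfft optional transform length (default next power of two).
#' @param eps_id excitation mask threshold, fraction of peak `|X|`.
#' @param window `"rectangular"` (default; transients fully contained) or
#'   `"exponential"` for noisy tails.
#' @param baseline_correct subtract each channel's pre-trigger mean first.
#' @return A `tf_estimate` with `method = "raw-ratio"` and coherence 1.
#' @export
estimate_transfer_raw <- function(trial, nfft = NULL, eps_id = 1e-3,
                                  window = "rectangular",
                                  baseline_correct = TRUE) {
  estimate_transfer_h1(list(trial), nfft = nfft, eps_id = eps_id,
                       window = window, baseline_correct = baseline_correct,
                       .method = "raw-ratio")
}

#' H1 ensemble-averaged transfer-function estimate with coherence
#'
#' `H1 = S_xy / S_xx` from cross- and auto-spectra averaged over repeated
#' strikes, with the per-bin coherence `gamma^2 = |S_xy|^2 / (S_xx S_yy)`.
#' Averaging suppresses measurement noise on the transmitted channel; the
#' coherence reports, per frequency, how much of the output is linearly
#' explained by the input. A single trial degenerates to the raw ratio.
#'
#' @param trials list of `impact_trial` objects sharing fs and length.
#' @inheritParams estimate_transfer_raw
#' @param .method internal method tag override.
#' @return A `tf_estimate` with `method = "h1-averaged"`.
#' @export
estimate_transfer_h1 <- function(trials, nfft = NULL, eps_id = 1e-3,
                                 window = "rectangular",
                                 baseline_correct = TRUE,
                                 .method = "h1-averaged") {
  if (inherits(trials, "impact_trial")) trials <- list(trials)
  stopifnot(length(trials) >= 1L,
            all(vapply(trials, inherits, logical(1), "impact_trial")))
  fs <- vapply(trials, function(tr) tr$x$fs, numeric(1))
  if (length(unique(fs)) != 1L)
    stop("trials disagree on sampling rate: ",
         paste(unique(fs), collapse = ", "), " Hz", call. = FALSE)
  fs <- fs[1L]
  nmax <- max(vapply(trials, function(tr) length(tr$x$samples), integer(1)))
  if (is.null(nfft)) nfft <- next_pow2(nmax)
  nfft <- as.integer(nfft)
  if (nfft < nmax || nfft %% 2L != 0L)
    stop("'nfft' must be even and >= the longest trial (", nmax, ")",
         call. = FALSE)
  nb <- nfft %/% 2L + 1L
  Sxx <- Syy <- numeric(nb)
  Sxy <- complex(nb)
  for (tr in trials) {
    ch <- if (baseline_correct) baseline_correct_trial(tr)
          else list(x = tr$x$samples, y = tr$y$samples)
    w <- trial_window(length(ch$x), window)
    X <- stats::fft(c(ch$x * w, numeric(nfft - length(ch$x))))[seq_len(nb)]
    Y <- stats::fft(c(ch$y * w, numeric(nfft - length(ch$y))))[seq_len(nb)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + Conj(X) * Y
  }
  m <- length(trials)
  Sxx <- Sxx / m; Syy <- Syy / m; Sxy <- Sxy / m
  if (max(Sxx) == 0)
    stop("reference channel is identically zero; nothing to identify",
         call. = FALSE)
  masked <- sqrt(Sxx) < eps_id * sqrt(max(Sxx))
  H <- rep(0 + 0i, nb)
  H[!masked] <- Sxy[!masked] / Sxx[!masked]
  coh <- rep(1, nb)
  if (.method == "h1-averaged" && m >= 1L) {
    ok <- !masked & Syy > 0
    coh[ok] <- Mod(Sxy[ok])^2 / (Sxx[ok] * Syy[ok])
    coh[!ok] <- 0
    coh[masked] <- 0
  }
  tf_estimate(force_spectrum(H, fs = fs, nfft = nfft),
              coherence = if (.method == "raw-ratio") 1 else coh,
              masked = masked, method = .method, n_trials = m)
}
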