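#' Uniformly sampled force time series
#'
#' The basic container used throughout the package: a vector of force samples
#' in newtons together with its sampling rate. Record duration is always
#' derived as `length(samples) / fs`, never stored.
#'
#' @param samples numeric vector of force values (N); must be finite, length
#'   at least 1.
#' @param fs sampling rate in Hz; must be positive.
#' @param label free-text channel name.
#' @return An object of class `force_signal` with fields `samples`, `fs`,
#'   `label`.
#' @examples
#' s <- force_signal(sin(2 * pi * 5 * (0:1023) / 1024), fs = 1024, label = "demo")
#' duration(s)
#' @export
force_signal <- function(samples, fs, label = "force") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("'samples' must contain at least one value", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must be finite (found NA/NaN/Inf at index ",
         which(!is.finite(samples))[1L], ")", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  structure(list(samples = samples, fs = as.numeric(fs),
                 label = as.character(label)[1L]),
            class = "force_signal")
}

#' @export
print.force_signal <- function(x, ...) {
  cat(sprintf("<force_signal> '%s': %d samples @ %g Hz (%.4g s)\n",
              x$label, length(x$samples), x$fs, duration(x)))
  cat(sprintf("  range [%.4g, %.4g] N, mean %.4g N\n",
              min(x$samples), max(x$samples), mean(x$samples)))
  invisible(x)
}

#' @export
length.force_signal <- function(x) length(x$samples)

#' Record duration in seconds
#' @param x a `force_signal`.
#' @return Duration `length(x) / fs` in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "force_signal"))
  length(x$samples) / x$fs
}

#' Sample time axis
#' @param x a `force_signal`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "force_signal"))
  (seq_along(x$samples) - 1L) / x$fs
}

#' Sum force channels sample by sample
#'
#' Total transmitted force of a multi-transducer mount is the elementwise sum
#' of the individual load-cell channels (e.g. the four under-frame sensors of
#' an instrumented treadmill).
#'
#' @param channels a list of `force_signal` objects sharing sampling rate and
#'   length (a single `force_signal` is accepted and returned unchanged).
#' @return A `force_signal` holding the elementwise sum, labelled with the
#'   combined channel names.
#' @export
sum_channels <- function(channels) {
  if (inherits(channels, "force_signal")) return(channels)
  if (!is.list(channels) || length(channels) == 0L ||
      !all(vapply(channels, inherits, logical(1), "force_signal")))
    stop("'channels' must be a non-empty list of force_signal objects",
         call. = FALSE)
  if (length(channels) == 1L) return(channels[[1L]])
  fs <- vapply(channels, function(s) s$fs, numeric(1))
  n <- vapply(channels, function(s) length(s$samples), integer(1))
  if (length(unique(fs)) != 1L)
    stop("channels disagree on sampling rate: ",
         paste(unique(fs), collapse = ", "), " Hz", call. = FALSE)
  if (length(unique(n)) != 1L)
    stop("channels disagree on length: ",
         paste(unique(n), collapse = ", "), call. = FALSE)
  total <- Reduce(`+`, lapply(channels, function(s) s$samples))
  force_signal(total, fs = fs[1L],
               label = paste(vapply(channels, function(s) s$label,
                                    character(1)), collapse = "+"))
}
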