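#' Read force channels from CSV
#'
#' Reads a plain-text CSV of sampled force data: a header row, a first column
#' of time in seconds (conventionally named `time_s`) or sample index, and one
#' numeric column per force channel in newtons. Lines starting with `#` are
#' ignored, so files written by [write_force_csv()] (which carry a
#' `# fs_hz=<value>` sidecar comment) round-trip.
#'
#' The sampling rate is the reciprocal of the median time step and the grid
#' must be uniform: any step deviating from the median by more than 1e-6
#' relative is rejected, naming the worst row.
#'
#' @param path CSV file path.
#' @param fs_override optional sampling rate in Hz; skips inference from the
#'   time column (use when the first column is a bare sample index).
#' @return Named list of `force_signal` objects, one per channel column.
#' @export
read_force_csv <- function(path, fs_override = NULL) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (ncol(df) < 2L)
    stop("'", path, "' needs a time/index column plus at least one channel",
         call. = FALSE)
  for (j in seq_len(ncol(df))) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1L]
      stop("non-numeric cell in '", path, "' at data row ",
           if (is.na(bad)) "?" else bad, ", column '", names(df)[j], "'",
           call. = FALSE)
    }
    if (anyNA(v))
      stop("missing value in '", path, "' at data row ", which(is.na(v))[1L],
           ", column '", names(df)[j], "'", call. = FALSE)
  }
  if (is.null(fs_override)) {
    tcol <- df[[1L]]
    if (nrow(df) < 2L)
      stop("cannot infer sampling rate from a single row; pass fs_override",
           call. = FALSE)
    dt <- diff(tcol)
    step <- stats::median(dt)
    if (step <= 0)
      stop("time column in '", path, "' is not strictly increasing",
           call. = FALSE)
    rel <- abs(dt - step) / step
    if (max(rel) > 1e-6) {
      worst <- which.max(rel)
      stop(sprintf(
        "non-uniform time grid in '%s': step into row %d is %.9g s (median %.9g s, %.3g%% off)",
        path, worst + 1L, dt[worst], step, 100 * rel[worst]), call. = FALSE)
    }
    fs <- 1 / step
  } else {
    fs <- fs_override
  }
  chans <- names(df)[-1L]
  out <- lapply(chans, function(nm) force_signal(df[[nm]], fs = fs, label = nm))
  names(out) <- chans
  out
}

#' Write force channels to CSV
#'
#' Emits a `# fs_hz=<value>` sidecar comment, a header row, a `time_s` column
#' and one column per channel. The inverse of [read_force_csv()].
#'
#' @param signals a `force_signal` or list of them (equal fs and length).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(signals, path) {
  if (inherits(signals, "force_signal")) signals <- list(signals)
  stopifnot(length(signals) >= 1L,
            all(vapply(signals, inherits, logical(1), "force_signal")))
  fs <- signals[[1L]]$fs
  n <- length(signals[[1L]]$samples)
  for (s in signals)
    if (s$fs != fs || length(s$samples) != n)
      stop("all channels must share fs and length", call. = FALSE)
  labs <- vapply(signals, function(s) s$label, character(1))
  labs <- make.unique(labs)
  df <- data.frame(time_s = (seq_len(n) - 1L) / fs)
  for (i in seq_along(signals)) df[[labs[i]]] <- signals[[i]]$samples
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g", fs), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a transfer-function estimate to CSV
#'
#' Columns `f_hz, re, im, coherence, masked` plus a `#` comment carrying
#' `fs_hz`, `nfft`, `method` and `n_trials`, so [read_transfer_csv()] can
#' reconstruct the estimate exactly.
#'
#' @param tf a `tf_estimate` (see [estimate_transfer_h1()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transfer_csv <- function(tf, path) {
  stopifnot(inherits(tf, "tf_estimate"))
  sp <- tf$spectrum
  df <- data.frame(f_hz = spectrum_freqs(sp),
                   re = Re(sp$values), im = Im(sp$values),
                   coherence = tf$coherence,
                   masked = as.integer(tf$masked))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g nfft=%d method=%s n_trials=%d",
                     sp$fs, sp$nfft, tf$method, tf$n_trials), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a transfer-function estimate from CSV
#'
#' @param path file written by [write_transfer_csv()].
#' @return A `tf_estimate`.
#' @export
read_transfer_csv <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list(fs = NA_real_, nfft = NA_integer_,
               method = "raw-ratio", n_trials = 1L)
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1L]]
    for (item in kv) {
      p <- strsplit(item, "=", fixed = TRUE)[[1L]]
      meta[[switch(p[1L], fs_hz = "fs", nfft = "nfft",
                   method = "method", n_trials = "n_trials", p[1L])]] <- p[2L]
    }
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("f_hz", "re", "im", "coherence", "masked")
  if (!all(need %in% names(df)))
    stop("'", path, "' is not a transfer-function CSV (needs columns ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  fs <- as.numeric(meta$fs)
  nfft <- as.integer(meta$nfft)
  if (!is.finite(fs)) fs <- 2 * max(df$f_hz)
  if (is.na(nfft)) nfft <- 2L * (nrow(df) - 1L)
  sp <- force_spectrum(complex(real = df$re, imaginary = df$im),
                       fs = fs, nfft = nfft)
  tf_estimate(sp, coherence = df$coherence, masked = df$masked > 0,
              method = as.character(meta$method),
              n_trials = as.integer(meta$n_trials))
}
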