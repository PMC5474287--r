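# All generators are pure functions of (parameters, seed): RNG state is
# localized and restored on exit.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Gait-synthesis parameters for walk-on-the-spot trials
#'
#' Study conditions for the synthetic evaluation-phase input: a vertical GRF
#' record of a subject stepping in place. Defaults: a 73.1 kg adult
#' (`body_weight` 717 N), 2 steps per second, 20 s record at the acquisition
#' settings of the measurement chain.
#'
#' The waveform is a body-weight baseline plus one stance profile per step —
#' two raised-cosine lobes (weight acceptance and push-off) and a brief,
#' sharper initial-contact transient, which is what gives real vertical GRF
#' its 5–30 Hz spectral tail.
#'
#' @param body_weight body weight in N (> 0).
#' @param step_frequency steps per second (Hz).
#' @param duration record length in s (default 20).
#' @param bump_sharpness dimensionless; > 1 narrows the stance lobes,
#'   widening the spectrum.
#' @param left_right_asymmetry fractional amplitude difference between
#'   alternating steps.
#' @param heel_transient amplitude of the initial-contact spike relative to
#'   the stance-lobe peak (0 disables it). The spike is ~10 ms half-width at
#'   the default cadence, which is what extends the spectrum into the
#'   30-80 Hz range where the treadmill modes live.
#' @param noise_sigma additive white sensor noise, N standard deviation.
#' @param seed integer seed; generation is a pure function of (params, seed).
#' @return An object of class `gait_params`.
#' @export
gait_params <- function(body_weight = 717, step_frequency = 2, duration = 20,
                        bump_sharpness = 1, left_right_asymmetry = 0,
                        heel_transient = 1, noise_sigma = 0, seed = NULL) {
  if (body_weight <= 0) stop("'body_weight' must be > 0 N", call. = FALSE)
  if (step_frequency <= 0) stop("'step_frequency' must be > 0 Hz", call. = FALSE)
  if (duration <= 0) stop("'duration' must be > 0 s", call. = FALSE)
  if (bump_sharpness <= 0) stop("'bump_sharpness' must be > 0", call. = FALSE)
  structure(list(body_weight = body_weight, step_frequency = step_frequency,
                 duration = duration, bump_sharpness = bump_sharpness,
                 left_right_asymmetry = left_right_asymmetry,
                 heel_transient = heel_transient,
                 noise_sigma = noise_sigma, seed = seed),
            class = "gait_params")
}

raised_cosine <- function(phase, center, halfwidth) {
  d <- phase - center
  ifelse(abs(d) < halfwidth, 0.5 * (1 + cos(pi * d / halfwidth)), 0)
}

#' Synthesize a walk-on-the-spot vertical GRF record
#'
#' Deterministic given `(params, seed)`. With zero noise and zero asymmetry
#' the signal is exactly periodic at the step period. The time mean equals
#' the body weight by construction (the stance fluctuation is zero-mean
#' before noise).
#'
#' @param params a [gait_params()].
#' @param fs sampling rate (Hz), default 1024.
#' @return A nonnegative `force_signal` of `duration * fs` samples.
#' @export
synth_walk_grf <- function(params = gait_params(), fs = 1024) {
  stopifnot(inherits(params, "gait_params"))
  n <- round(params$duration * fs)
  t <- (0:(n - 1L)) / fs
  phase <- (t * params$step_frequency) %% 1
  w <- min(0.11 / params$bump_sharpness, 0.30)
  p <- raised_cosine(phase, 0.30, w) + 0.92 * raised_cosine(phase, 0.70, w)
  if (params$heel_transient > 0) {
    # initial-contact spike: 10 ms half-width at a 0.5 s step period, so its
    # spectrum rolls off by ~60-80 Hz as heel-strike transients do
    p <- p + params$heel_transient * raised_cosine(phase, 0.115, 0.02)
  }
  fluct <- 0.9 * (p - mean(p))
  if (params$left_right_asymmetry != 0) {
    side <- 1 + params$left_right_asymmetry * (-1)^floor(t * params$step_frequency)
    fluct <- fluct * side
  }
  x <- params$body_weight * (1 + fluct)
  if (params$noise_sigma > 0)
    x <- x + with_local_seed(params$seed,
                             stats::rnorm(n, 0, params$noise_sigma))
  force_signal(pmax(x, 0), fs = fs, label = "grf")
}

#' Synthesize a hammer-strike force pulse
#'
#' A single half-sine pulse of the given peak and base width at a randomized
#' onset, zero elsewhere, plus an optional white noise floor. The sampled
#' pulse is rescaled so its discrete time integral equals the analytic
#' half-sine impulse `peak * width * 2 / pi` exactly (the impulse, not the
#' sampled peak, is what drives broadband excitation); the realized peak
#' deviates from nominal by under 1%.
#'
#' @param fs sampling rate (Hz).
#' @param peak nominal pulse peak (N).
#' @param width_ms pulse base width in milliseconds. The default 5 ms keeps
#'   the first spectral null (at `1.5 / width`) well above the 150 Hz
#'   analysis band.
#' @param record_s record length (s).
#' @param seed integer seed (onset randomization).
#' @param noise_sigma white noise floor (N sd), default 0.
#' @param onset_s optional fixed onset time (overrides randomization).
#' @return A `force_signal`.
#' @export
synth_hammer_impact <- function(fs = 1024, peak = 500, width_ms = 5,
                                record_s = 2, seed = NULL, noise_sigma = 0,
                                onset_s = NULL) {
  w <- width_ms / 1000
  if (w >= record_s) stop("pulse wider than the record", call. = FALSE)
  n <- round(record_s * fs)
  margin <- min(0.1, 0.25 * record_s)
  onset <- onset_s %||% with_local_seed(seed,
    stats::runif(1, margin, record_s - w - margin))
  onset <- round(onset * fs) / fs
  t <- (0:(n - 1L)) / fs
  x <- numeric(n)
  inpulse <- t > onset & t < onset + w
  x[inpulse] <- sin(pi * (t[inpulse] - onset) / w)
  area <- sum(x) / fs
  if (area > 0) x <- x * (peak * w * 2 / pi) / area
  if (noise_sigma > 0)
    x <- x + with_local_seed(if (is.null(seed)) NULL else seed + 1L,
                             stats::rnorm(n, 0, noise_sigma))
  force_signal(x, fs = fs, label = "hammer")
}

#' Ground-truth treadmill transmission model
#'
#' A weighted sum of damped second-order modes with exactly unit (or given)
#' static gain — the simulator's stand-in for a real frame's multi-resonant
#' force-transmission dynamics: flat at low frequency, oscillatory above the
#' first structural mode. Mode weights are normalized to sum to 1 so that
#' `H(0) = static_gain` holds exactly and body weight transmits undistorted.
#'
#' @param modes `data.frame` (or matrix) with columns `fn` (Hz, > 0), `xi`
#'   (> 0) and `weight` (> 0; normalized internally).
#' @param static_gain DC gain (default 1).
#' @return An object of class `treadmill_model`.
#' @export
treadmill_model <- function(modes = data.frame(fn = c(28, 65, 110),
                                               xi = c(0.04, 0.05, 0.06),
                                               weight = c(0.55, 0.3, 0.15)),
                            static_gain = 1) {
  modes <- as.data.frame(modes)
  stopifnot(all(c("fn", "xi", "weight") %in% names(modes)))
  if (any(modes$fn <= 0) || any(modes$xi <= 0) || any(modes$weight <= 0))
    stop("modes need fn > 0, xi > 0, weight > 0", call. = FALSE)
  modes$weight <- modes$weight / sum(modes$weight)
  structure(list(modes = modes, static_gain = static_gain),
            class = "treadmill_model")
}

#' @export
print.treadmill_model <- function(x, ...) {
  cat(sprintf("<treadmill_model> %d mode(s), static gain %g\n",
              nrow(x$modes), x$static_gain))
  for (i in seq_len(nrow(x$modes)))
    cat(sprintf("  fn = %6.2f Hz, xi = %.3f, weight = %.3f\n",
                x$modes$fn[i], x$modes$xi[i], x$modes$weight[i]))
  invisible(x)
}

#' Frequency response of a treadmill model
#'
#' `H(f) = static_gain * sum_i weight_i / (1 - (f/fn_i)^2 + 2i xi_i f/fn_i)`.
#' Exactly `static_gain` at `f = 0`.
#'
#' @param model a `treadmill_model`.
#' @param freqs numeric frequency vector (Hz), or a `force_spectrum` template.
#' @return Complex response values (a `force_spectrum` when given a template).
#' @export
treadmill_response <- function(model, freqs) {
  stopifnot(inherits(model, "treadmill_model"))
  template <- NULL
  if (inherits(freqs, "force_spectrum")) {
    template <- freqs
    freqs <- spectrum_freqs(freqs)
  }
  H <- rep(0 + 0i, length(freqs))
  for (i in seq_len(nrow(model$modes))) {
    u <- freqs / model$modes$fn[i]
    H <- H + model$modes$weight[i] /
      complex(real = 1 - u^2, imaginary = 2 * model$modes$xi[i] * u)
  }
  H <- model$static_gain * H
  if (!is.null(template))
    force_spectrum(H, fs = template$fs, nfft = template$nfft)
  else H
}

#' Exact transfer-function estimate of a treadmill model
#'
#' Samples the model's analytic response on a transform grid and wraps it as
#' an unmasked `tf_estimate` — the oracle against which identified estimates
#' and the compensation round trip are checked.
#'
#' @param model a `treadmill_model`.
#' @param fs sampling rate (Hz).
#' @param nfft transform length (even).
#' @return A `tf_estimate` with coherence 1 and no masked bins.
#' @export
exact_transfer <- function(model, fs, nfft) {
  sp <- force_spectrum(rep(0 + 0i, nfft %/% 2 + 1L), fs = fs, nfft = nfft)
  tf_estimate(treadmill_response(model, sp), coherence = 1, masked = FALSE,
              method = "raw-ratio", n_trials = 1L)
}

#' Pass a force signal through the treadmill transmission
#'
#' Spectral application of the model response (circular at `nfft =` signal
#' length by default), plus optional white measurement noise on the
#' transmitted channel — the forward model that turns true track-surface
#' force into what the under-frame load cells report.
#'
#' @param x input `force_signal` (true force on the track).
#' @param model a `treadmill_model`.
#' @param noise_sigma white measurement noise (N sd).
#' @param seed integer seed for the noise.
#' @param nfft optional transform length.
#' @return The transmitted `force_signal` `y`, same length as `x`.
#' @export
apply_transmission <- function(x, model, noise_sigma = 0, seed = NULL,
                               nfft = NULL) {
  stopifnot(inherits(x, "force_signal"), inherits(model, "treadmill_model"))
  y <- apply_frf(x, function(f) treadmill_response(model, f), nfft = nfft,
                 label = "loadcell_sum")
  if (noise_sigma > 0)
    y$samples <- y$samples +
      with_local_seed(seed, stats::rnorm(length(y$samples), 0, noise_sigma))
  y
}

#' Generate a hammer-strike identification dataset
#'
#' Independent strikes with randomized onsets and peak jitter; each trial's
#' reference `x` is a clean half-sine pulse (plus optional platform noise)
#' and `y` is the pulse passed through the treadmill model plus measurement
#' noise. Deterministic given `seed`.
#'
#' @param model a `treadmill_model`.
#' @param n_strikes number of trials (>= 1).
#' @param fs sampling rate (Hz).
#' @param peak nominal pulse peak (N); jittered +/-10% per strike.
#' @param width_ms pulse base width (ms).
#' @param record_s per-trial record length (s).
#' @param noise_sigma_x platform (reference) noise sd, default 0 — the
#'   platform is treated as truth.
#' @param noise_sigma_y load-cell (transmitted) noise sd.
#' @param seed integer seed.
#' @return List of `impact_trial` objects.
#' @export
make_identification_dataset <- function(model, n_strikes = 10, fs = 1024,
                                        peak = 500, width_ms = 5,
                                        record_s = 2, noise_sigma_x = 0,
                                        noise_sigma_y = 0, seed = 1) {
  stopifnot(n_strikes >= 1)
  with_local_seed(seed, {
    lapply(seq_len(n_strikes), function(i) {
      pk <- peak * stats::runif(1, 0.9, 1.1)
      onset <- stats::runif(1, min(0.1, 0.25 * record_s),
                            record_s - width_ms / 1000 - min(0.1, 0.25 * record_s))
      x <- synth_hammer_impact(fs = fs, peak = pk, width_ms = width_ms,
                               record_s = record_s, onset_s = onset)
      y <- apply_transmission(x, model)
      if (noise_sigma_y > 0)
        y$samples <- y$samples + stats::rnorm(length(y$samples), 0,
                                              noise_sigma_y)
      if (noise_sigma_x > 0)
        x$samples <- x$samples + stats::rnorm(length(x$samples), 0,
                                              noise_sigma_x)
      impact_trial(x, y)
    })
  })
}
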