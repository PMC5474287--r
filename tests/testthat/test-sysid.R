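test_that("impact detection segments strikes and handles silence", {
  pulse <- synth_hammer_impact(peak = 200, width_ms = 10, record_s = 1,
                               onset_s = 0.4)
  seg <- detect_impacts(pulse, threshold = 50)
  expect_equal(nrow(seg), 1L)
  pk <- which.max(pulse$samples)
  expect_true(seg[1, "start"] <= pk && pk <= seg[1, "end"])
  silent <- force_signal(numeric(1024), fs_std)
  expect_equal(nrow(detect_impacts(silent, threshold = 10)), 0L)
})

test_that("impact segments merge when windows overlap and split when apart", {
  fs <- fs_std
  x <- numeric(3 * fs)
  put <- function(x, onset_s, width_s = 0.01) {
    idx <- round(onset_s * fs) + seq_len(round(width_s * fs))
    x[idx] <- 200 * sin(pi * seq_along(idx) / length(idx))
    x
  }
  far <- force_signal(put(put(x, 0.5), 2.0), fs)
  segs <- detect_impacts(far, 50, pre_window = 0.05, post_window = 0.3)
  expect_equal(nrow(segs), 2L)
  near <- force_signal(put(put(x, 0.5), 0.7), fs)
  segs <- detect_impacts(near, 50, pre_window = 0.05, post_window = 0.3)
  expect_equal(nrow(segs), 1L)
})

test_that("raw ratio recovers trivial systems exactly", {
  x <- synth_hammer_impact(peak = 300, width_ms = 8, record_s = 1,
                           onset_s = 0.3)
  tf <- estimate_transfer_raw(impact_trial(x, x))
  ok <- !tf$masked
  expect_gt(mean(ok), 0.2) # broad excitation
  expect_rel_equal(tf$spectrum$values[ok], rep(1 + 0i, sum(ok)), 1e-9)
})

test_that("a pure delay identifies as unit magnitude and linear phase", {
  x <- synth_hammer_impact(peak = 300, width_ms = 8, record_s = 2,
                           onset_s = 0.5)
  d <- 13L
  y <- force_signal(c(numeric(d), x$samples[1:(length(x$samples) - d)]),
                    fs_std)
  tf <- estimate_transfer_raw(impact_trial(x, y))
  ok <- !tf$masked
  f <- spectrum_freqs(tf$spectrum)[ok]
  expected <- exp(-2i * pi * f * d / fs_std)
  expect_rel_equal(Mod(tf$spectrum$values[ok]), rep(1, sum(ok)), 1e-6)
  expect_rel_equal(tf$spectrum$values[ok], expected, 1e-6)
})

test_that("raw ratio recovers a second-order transmission in closed form", {
  x <- synth_hammer_impact(peak = 400, width_ms = 5, record_s = 2,
                           onset_s = 0.6)
  prm <- second_order_params(45, 0.05)
  y <- apply_second_order(x, prm)
  tf <- estimate_transfer_raw(impact_trial(x, y))
  f <- spectrum_freqs(tf$spectrum)
  sel <- !tf$masked & f <= 150
  Htrue <- second_order_frf(f[sel] / 45, 0.05)
  expect_lt(max(Mod(tf$spectrum$values[sel] - Htrue) / Mod(Htrue)), 0.02)
})

test_that("x identically zero is rejected", {
  z <- force_signal(numeric(512), fs_std)
  y <- force_signal(rnorm(512), fs_std)
  expect_error(estimate_transfer_raw(impact_trial(z, y)), "zero")
})

test_that("H1 degenerates to the raw ratio for one noiseless trial", {
  set.seed(11)
  x <- synth_hammer_impact(peak = 350, width_ms = 6, record_s = 1,
                           onset_s = 0.3)
  y <- apply_transmission(x, small_model())
  trial <- impact_trial(x, y)
  h1 <- estimate_transfer_h1(list(trial))
  raw <- estimate_transfer_raw(trial)
  ok <- !h1$masked
  expect_equal(h1$masked, raw$masked)
  expect_rel_equal(h1$spectrum$values[ok], raw$spectrum$values[ok], 1e-9)
})

test_that("H1 averaging over noisy strikes recovers the modal response", {
  model <- small_model()
  trials <- make_identification_dataset(model, n_strikes = 20,
                                        record_s = 2, noise_sigma_y = 0.5,
                                        seed = 21)
  # output SNR ~20 dB relative to the transmitted pulse RMS
  tf <- estimate_transfer_h1(trials)
  f <- spectrum_freqs(tf$spectrum)
  for (fn in model$modes$fn) {
    sel <- !tf$masked & abs(f - fn) < 2
    Htrue <- treadmill_response(model, f[sel])
    relerr <- Mod(tf$spectrum$values[sel] - Htrue) / Mod(Htrue)
    expect_lt(max(relerr), 0.05)
  }
  excited <- !tf$masked & f <= 150
  expect_gt(stats::median(tf$coherence[excited]), 0.95)
})

test_that("uncorrelated output gives near-zero coherence", {
  set.seed(31)
  trials <- lapply(1:20, function(i) {
    x <- synth_hammer_impact(peak = 300, width_ms = 6, record_s = 1, seed = i)
    y <- force_signal(rnorm(length(x$samples)), fs_std)
    impact_trial(x, y)
  })
  tf <- estimate_transfer_h1(trials)
  f <- spectrum_freqs(tf$spectrum)
  band <- !tf$masked & f > 5 & f <= 150
  expect_lt(stats::median(tf$coherence[band]), 0.2)
})

test_that("coherence is invariant to channel rescaling", {
  model <- small_model()
  trials <- make_identification_dataset(model, n_strikes = 5, record_s = 1,
                                        noise_sigma_y = 1, seed = 41)
  tf1 <- estimate_transfer_h1(trials)
  scaled <- lapply(trials, function(tr)
    impact_trial(force_signal(3.7 * tr$x$samples, tr$x$fs),
                 force_signal(-0.4 * tr$y$samples, tr$y$fs)))
  tf2 <- estimate_transfer_h1(scaled)
  ok <- !tf1$masked
  expect_rel_equal(tf2$coherence[ok], tf1$coherence[ok], 1e-9)
})

test_that("noiseless estimators recover any simulated linear system in band", {
  for (seed in c(101, 202)) {
    model <- random_model(seed)
    x <- synth_hammer_impact(peak = 400, width_ms = 5, record_s = 2,
                             onset_s = 0.5)
    y <- apply_transmission(x, model)
    # no static preload in this synthetic trial, so baseline correction is
    # disabled to test estimator exactness in isolation
    tf <- estimate_transfer_h1(list(impact_trial(x, y)),
                               baseline_correct = FALSE)
    X <- forward_spectrum(x, nfft = tf$spectrum$nfft)
    strong <- Mod(X$values) >= 0.01 * max(Mod(X$values))
    sel <- strong & !tf$masked
    sel[length(sel)] <- FALSE # Nyquist bin of a real sampling chain is real
    Htrue <- treadmill_response(model, spectrum_freqs(tf$spectrum)[sel])
    expect_lt(max(Mod(tf$spectrum$values[sel] - Htrue) / Mod(Htrue)), 0.01)
  }
})

test_that("transfer-function CSV round trip is lossless", {
  model <- small_model()
  trials <- make_identification_dataset(model, n_strikes = 3, record_s = 1,
                                        noise_sigma_y = 0.2, seed = 51)
  tf <- estimate_transfer_h1(trials)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transfer_csv(tf, path)
  back <- read_transfer_csv(path)
  expect_equal(back$method, tf$method)
  expect_equal(back$n_trials, tf$n_trials)
  expect_equal(back$masked, tf$masked)
  expect_rel_equal(back$spectrum$values, tf$spectrum$values, 1e-6)
  expect_equal(back$spectrum$nfft, tf$spectrum$nfft)
})
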