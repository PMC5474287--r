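make_tf <- function(values, fs = fs_std, masked = FALSE) {
  nfft <- 2L * (length(values) - 1L)
  tf_estimate(force_spectrum(values, fs = fs, nfft = nfft),
              coherence = 1, masked = masked, method = "raw-ratio",
              n_trials = 1L)
}

test_that("inversion of trivial responses is exact", {
  nb <- 129
  ones <- make_tf(rep(1 + 0i, nb))
  inv <- invert_transfer(ones, inversion_options(reg_eps = 0, f_max = 512))
  expect_rel_equal(inv$values, rep(1 + 0i, nb), 1e-12)
  twos <- make_tf(rep(2 + 0i, nb))
  inv2 <- invert_transfer(twos, inversion_options(reg_eps = 0, f_max = 512))
  expect_rel_equal(inv2$values, rep(0.5 + 0i, nb), 1e-12)
})

test_that("Tikhonov regularization bounds the inverse at deep antiresonances", {
  vals <- rep(1 + 0i, 129)
  vals[60] <- 1e-6 + 0i
  tf <- make_tf(vals)
  inv <- invert_transfer(tf, inversion_options(reg_eps = 1e-2, f_max = 512))
  # |Hinv| = |H| / (|H|^2 + lam^2) <= 1 / (2 lam), not 1e6
  lam <- 1e-2 * 1
  expect_lt(Mod(inv$values[60]), 1 / (2 * lam) + 1e-9)
  expect_lt(Mod(inv$values[60]), 1e4)
})

test_that("band limiting and masking zero the excluded bins", {
  vals <- rep(1 + 0i, 129)
  masked <- rep(FALSE, 129)
  masked[100] <- TRUE
  tf <- make_tf(vals, masked = masked)
  inv <- invert_transfer(tf, inversion_options(reg_eps = 0, f_max = 150))
  f <- fs_std / 256 * (0:128)
  expect_true(all(Mod(inv$values[f > 150]) == 0))
  expect_equal(Mod(inv$values[100]), 0)
  pass <- invert_transfer(tf, inversion_options(reg_eps = 0, f_max = 150,
                                                outside_band = "passthrough"))
  expect_true(all(inv_ok <- Mod(pass$values[f > 150 & !masked]) == 1))
  expect_error(invert_transfer(make_tf(vals, masked = TRUE)), "masked")
})

test_that("unit transfer function compensates to the identity", {
  set.seed(8)
  y <- force_signal(rnorm(256, 700, 30), fs_std)
  tf <- make_tf(rep(1 + 0i, 129))
  xc <- compensate(y, tf, inversion_options(reg_eps = 0, f_max = 512))
  expect_rel_equal(xc$samples, y$samples, 1e-9)
})

test_that("round trip through randomized modal transmissions is exact", {
  for (seed in c(5, 17, 29)) {
    model <- random_model(seed)
    x <- synth_walk_grf(gait_params(duration = 5, seed = seed))
    y <- apply_transmission(x, model)
    tf <- exact_transfer(model, x$fs, nfft = length(x$samples))
    xc <- compensate(y, tf, inversion_options(reg_eps = 0, f_max = x$fs / 2))
    expect_lt(thd(xc, x)$thd, 1e-6)
  }
})

test_that("compensation is linear in the measurement", {
  model <- small_model()
  tf <- exact_transfer(model, fs_std, nfft = 1024)
  set.seed(12)
  y1 <- force_signal(rnorm(1024), fs_std)
  y2 <- force_signal(rnorm(1024), fs_std)
  a <- 2.5; b <- -1.3
  opts <- inversion_options()
  mix <- force_signal(a * y1$samples + b * y2$samples, fs_std)
  lhs <- compensate(mix, tf, opts)$samples
  rhs <- a * compensate(y1, tf, opts)$samples +
    b * compensate(y2, tf, opts)$samples
  expect_rel_equal(lhs, rhs, 1e-9)
})

test_that("compensation improves on the uncompensated signal under noise", {
  model <- small_model()
  x <- synth_walk_grf(gait_params(duration = 10, seed = 3))
  y <- apply_transmission(x, model)
  snr_sigma <- stats::sd(y$samples - mean(y$samples)) / 10^(30 / 20)
  set.seed(99)
  yn <- force_signal(y$samples + rnorm(length(y$samples), 0, snr_sigma),
                     fs_std)
  tf <- exact_transfer(model, x$fs, nfft = length(x$samples))
  xc <- compensate(yn, tf, inversion_options(reg_eps = 1e-2))
  expect_lt(thd(xc, x)$thd, thd(yn, x)$thd)
})

test_that("zero-padding the measurement does not change the compensation", {
  # on the dynamic (zero-mean) component: the static level is handled
  # separately and is a property of the record, not of its padding
  model <- small_model()
  x <- synth_walk_grf(gait_params(duration = 4, seed = 6))
  y <- apply_transmission(x, model)
  y$samples <- y$samples - mean(y$samples)
  n <- length(y$samples)
  tf <- exact_transfer(model, x$fs, nfft = n)
  opts <- inversion_options(reg_eps = 0, f_max = x$fs / 2)
  base <- compensate(y, tf, opts, nfft = 2L * n)
  padded <- force_signal(c(y$samples, numeric(n)), y$fs)
  again <- compensate(padded, tf, opts, nfft = 2L * n)
  expect_rel_equal(again$samples[1:n], base$samples, 1e-9)
})

test_that("sampling-rate mismatch is rejected", {
  tf <- make_tf(rep(1 + 0i, 129), fs = 2048)
  y <- force_signal(rnorm(256), fs_std)
  expect_error(compensate(y, tf), "sampled at")
})

test_that("transfer functions are interpolated across differing grids", {
  model <- small_model()
  x <- synth_walk_grf(gait_params(duration = 10, seed = 4))
  y <- apply_transmission(x, model)
  # exact response, but on a much coarser grid than the measurement's
  coarse <- exact_transfer(model, x$fs, nfft = 4096)
  xc <- compensate(y, coarse, inversion_options(reg_eps = 0))
  expect_lt(thd(xc, x)$thd, 0.5 / 100)
})
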