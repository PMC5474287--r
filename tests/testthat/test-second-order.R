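test_that("closed-form amplitude response matches the structural benchmarks", {
  # a 45 Hz mount read at the 12.75 Hz GRF power edge overshoots by 8.7%
  expect_equal(round(amplitude_response(12.75 / 45, 0), 3), 1.087)
  expect_equal(round(amplitude_response(12.75 / 160, 0), 3), 1.006)
  expect_equal(round(amplitude_response(12.75 / 219, 0), 3), 1.003)
  expect_equal(amplitude_response(0, 0.3), 1)
  expect_equal(amplitude_response(1, 0.5), 1)
  expect_error(amplitude_response(1, 0), "resonance")
})

test_that("phase response uses the continuous 0 to -pi branch", {
  expect_equal(phase_response(0, 0.2), 0)
  expect_equal(phase_response(1, 0.3), -pi / 2)
  expect_lt(abs(phase_response(0.01, 0.1) - (-2 * 0.1 * 0.01)), 1e-5)
  # beyond resonance the phase keeps falling towards -pi
  expect_lt(phase_response(3, 0.1), -pi / 2)
  expect_equal(phase_response(1e6, 0.1), -pi, tolerance = 1e-3)
  u <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(phase_response(u, 0.2)) < 0))
})

test_that("amplitude and phase equal modulus and argument of the rational form", {
  u <- seq(0, 4, by = 0.05)
  for (xi in c(0.01, 0.1, 0.5, 1)) {
    H <- second_order_frf(u, xi)
    expect_rel_equal(amplitude_response(u, xi), Mod(H), 1e-12)
    expect_rel_equal(phase_response(u, xi), Arg(H), 1e-12)
  }
})

test_that("low-frequency limits hold to the stated tolerances", {
  u <- seq(1e-4, 0.01, length.out = 50)
  for (xi in c(0.01, 0.05, 0.2)) {
    expect_lt(max(abs(amplitude_response(u, xi) - 1)), 2e-4)
    expect_lt(max(abs(phase_response(u, xi) + 2 * xi * u)), 1e-5)
  }
})

test_that("natural frequency follows sqrt(stiffness/mass)/2pi", {
  expect_equal(natural_frequency(4 * pi^2, 1), 1)
  expect_equal(natural_frequency((2 * pi * 45)^2 * 150, 150), 45)
  expect_equal(natural_frequency(4e5, 100) / natural_frequency(1e5, 100), 2)
  expect_error(natural_frequency(-1, 10), "positive")
})

test_that("distortionless transfer is a pure gain and delay", {
  tmpl <- forward_spectrum(force_signal(numeric(256), fs_std))
  ones <- distortionless_transfer(distortionless_params(1, 0), tmpl)
  expect_rel_equal(Mod(ones$values), rep(1, 129), 1e-12)
  twos <- distortionless_transfer(distortionless_params(2, 0), tmpl)
  expect_rel_equal(twos$values, rep(2 + 0i, 129), 1e-12)
  # delay of d samples: multiply-and-invert equals a circular index shift
  set.seed(4)
  x <- force_signal(rnorm(256), fs_std)
  d <- 10L
  H <- distortionless_transfer(distortionless_params(1, d / fs_std),
                               spectrum_freqs(tmpl))
  y <- apply_frf(x, H)
  shifted <- x$samples[((seq_len(256) - 1L - d) %% 256L) + 1L] # oracle
  expect_rel_equal(y$samples, shifted, 1e-9)
})

test_that("second-order application is transparent far below resonance", {
  x <- sine_signal(5, n = 2 * fs_std)
  y <- apply_second_order(x, second_order_params(fn = 400, xi = 0.01))
  expect_rel_equal(y$samples, x$samples, 1e-3)
  z <- force_signal(numeric(512), fs_std)
  expect_equal(apply_second_order(z, second_order_params(45, 0.05))$samples,
               numeric(512))
})

test_that("spectral application matches time-domain ODE integration", {
  skip_if_not_installed("deSolve")
  # oracle: integrate xdd + 2 xi wn xd + wn^2 x = wn^2 u(t) from rest and
  # compare after the transient has decayed (periodic input, so the spectral
  # result is the exact steady state)
  fn <- 32; xi <- 0.15; wn <- 2 * pi * fn
  u <- multitone_signal(freqs = c(2, 7, 13, 21), duration = 4, seed = 5)
  ufun <- stats::approxfun(signal_time(u), u$samples, rule = 2)
  deriv <- function(t, s, p)
    list(c(s[2], wn^2 * (ufun(t) - s[1]) - 2 * xi * wn * s[2]))
  sol <- deSolve::lsoda(c(0, 0), signal_time(u), deriv, NULL,
                        rtol = 1e-9, atol = 1e-9)
  spectral <- apply_second_order(u, second_order_params(fn, xi))
  late <- signal_time(u) > 2 # > 30 decay time constants
  err <- sol[late, 2] - spectral$samples[late]
  expect_lt(sqrt(mean(err^2) / mean(spectral$samples[late]^2)), 0.01)
})

test_that("distortion sweep falls with mount frequency and rises as damping drops", {
  grf <- synth_walk_grf(gait_params(duration = 10, seed = 2))
  sw <- thd_sweep(grf, fn_grid = c(300, 100, 50), xi_list = c(0.05, 0.2))
  expect_equal(sw$fn_hz, rep(c(50, 100, 300), each = 2)) # sorted
  # far above the GRF band the mount is transparent
  bw <- bandwidth_98(grf)
  high <- thd_sweep(grf, 10 * bw, 0.05)$thd_percent
  expect_lt(high, 2)
  for (xi in c(0.05, 0.2)) {
    grid <- thd_sweep(grf, seq(2 * bw, 200, by = 20), xi)
    expect_true(all(diff(grid$thd_percent) <= 1e-9))
  }
  at45 <- thd_sweep(grf, 45, c(0.05, 0.2))
  expect_lt(at45$thd_percent[at45$xi == 0.2],
            at45$thd_percent[at45$xi == 0.05])
})
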