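# Shared builders for test fixtures; everything is generated in code.

fs_std <- 1024

sine_signal <- function(freq, fs = fs_std, n = 4 * fs, amp = 1) {
  force_signal(amp * sin(2 * pi * freq * (0:(n - 1)) / fs), fs = fs,
               label = paste0("sine", freq))
}

# periodic band-limited test input: integer-Hz sinusoids with fixed phases,
# exactly periodic over a 1 s block
multitone_signal <- function(freqs = c(2, 5, 9, 14), fs = fs_std,
                             duration = 4, amps = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(amps)) amps <- runif(length(freqs), 0.5, 1.5)
  phases <- runif(length(freqs), 0, 2 * pi)
  t <- (0:(duration * fs - 1)) / fs
  x <- rowSums(mapply(function(a, f, p) a * sin(2 * pi * f * t + p),
                      amps, freqs, phases))
  force_signal(x, fs = fs, label = "multitone")
}

small_model <- function() {
  treadmill_model(data.frame(fn = c(25, 55), xi = c(0.05, 0.06),
                             weight = c(0.6, 0.4)))
}

random_model <- function(seed) {
  set.seed(seed)
  k <- sample(2:3, 1)
  treadmill_model(data.frame(fn = sort(runif(k, 20, 60)) * c(1, 2.2, 4)[1:k],
                             xi = runif(k, 0.03, 0.08),
                             weight = runif(k, 0.2, 1)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) /
              max(max(abs(expected)), .Machine$double.eps), tol)
}
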