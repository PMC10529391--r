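test_that("zero damping gives a pure non-decaying sinusoid at omega_n", {
  wn <- 2 * pi * 2e6
  g <- 3e-7
  y <- simulate_pa_signal(second_order_params(wn, 0, gain = g),
                          ts = 1 / (40 * 2e6), n_samples = 4000)
  t <- signal_time(y)
  expect_equal(y$samples, g * wn * sin(wn * t), tolerance = 1e-12)
  # no decay: late peaks as tall as early ones
  expect_equal(max(abs(y$samples[3000:4000])), g * wn, tolerance = 1e-3)
})

test_that("simulation is reproducible and starts at zero on the delay instant", {
  p <- ring_params(zeta = 0.35)
  a <- simulate_pa_signal(p, ts = 1e-8, n_samples = 500, delay = 1e-6,
                          noise_snr_db = 25, seed = 11)
  b <- simulate_pa_signal(p, ts = 1e-8, n_samples = 500, delay = 1e-6,
                          noise_snr_db = 25, seed = 11)
  expect_identical(a$samples, b$samples)
  clean <- simulate_pa_signal(p, ts = 1e-8, n_samples = 500, delay = 1e-6)
  k_delay <- 1 + 1e-6 / 1e-8
  expect_identical(clean$samples[1:(k_delay - 1)], rep(0, k_delay - 1))
  expect_equal(clean$samples[k_delay], 0)
})

test_that("log decrement of successive positive peaks matches 2*pi*zeta/sqrt(1-zeta^2)", {
  zeta <- 0.3
  y <- simulate_pa_signal(second_order_params(2 * pi * 2.25e6, zeta, gain = 1),
                          ts = 1e-8, n_samples = 4000)
  s <- y$samples
  n <- length(s)
  peaks <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n] &
                   s[2:(n - 1)] > 0) + 1L
  expect_gte(length(peaks), 4)
  decrements <- log(s[peaks[-length(peaks)]] / s[peaks[-1]])
  expect_equal(decrements,
               rep(2 * pi * zeta / sqrt(1 - zeta^2), length(decrements)),
               tolerance = 1e-3)
})

test_that("noise level honors the stated SNR over the signal support", {
  p <- ring_params(zeta = 0.2)
  clean <- simulate_pa_signal(p, ts = 1e-8, n_samples = 5000)
  noisy <- simulate_pa_signal(p, ts = 1e-8, n_samples = 5000,
                              noise_snr_db = 20, seed = 5)
  noise <- noisy$samples - clean$samples
  snr_est <- 20 * log10(sqrt(mean(clean$samples^2)) / sd(noise))
  expect_equal(snr_est, 20, tolerance = 0.5)
})

test_that("unsupported regimes are rejected", {
  expect_error(simulate_pa_signal(second_order_params(1e7, 1.2), 1e-8, 100),
               "underdamped")
  expect_error(simulate_pa_signal(second_order_params(1e7, 0.3), 1e-6, 100),
               "aliasing")
  expect_error(second_order_params(-1, 0.3), "omega_n")
})

test_that("oscillation peak amplitudes decay monotonically iff zeta > 0", {
  peak_heights <- function(zeta) {
    y <- simulate_pa_signal(second_order_params(2 * pi * 2e6, zeta, gain = 1),
                            ts = 1 / (50 * 2e6), n_samples = 3000)
    s <- abs(y$samples)
    n <- length(s)
    idx <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
    s[idx]
  }
  expect_true(all(diff(peak_heights(0.15)) < 0))
  expect_equal(diff(peak_heights(0)), rep(0, length(peak_heights(0)) - 1),
               tolerance = 1e-6)
})

test_that("discretize produces the exact eigenvalue map and matching impulse response", {
  p <- second_order_params(1e7, 0.2, gain = 2e-7)
  ts <- 1e-8
  m <- discretize(p, ts)
  ev <- eigen(m$A, only.values = TRUE)$values
  wd <- 1e7 * sqrt(1 - 0.2^2)
  lam <- exp(complex(real = -0.2 * 1e7, imaginary = wd) * ts)
  expect_equal(sort(Mod(ev)), rep(Mod(lam), 2), tolerance = 1e-12)
  expect_equal(max(Im(ev)), Im(lam), tolerance = 1e-12)
  # sampled impulse response equals the closed form
  h <- impulse_response(m, 50)
  hc <- simulate_pa_signal(p, ts, 50)$samples
  expect_equal(h, hc, tolerance = 1e-9)
  # zeta = 0 puts the poles exactly on the unit circle
  m0 <- discretize(second_order_params(1e7, 0), ts)
  expect_equal(Mod(eigen(m0$A, only.values = TRUE)$values), c(1, 1))
  # ts -> 0: eigenvalues -> 1
  mt <- discretize(p, 1e-15)
  expect_equal(eigen(mt$A, only.values = TRUE)$values,
               as.complex(c(1, 1)), tolerance = 1e-6)
})

test_that("discretize/extract round trip is the identity over the underdamped grid", {
  for (zeta in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
    for (wnts in c(0.01, 0.1, 0.5, 1)) {
      wn <- 1e7
      ts <- wnts / wn
      est <- extract_modal_params(discretize(second_order_params(wn, zeta), ts)$A, ts)
      expect_equal(est$omega_n, wn, tolerance = 1e-9)
      expect_equal(est$zeta, zeta, tolerance = 1e-9)
    }
  }
})
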