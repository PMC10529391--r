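test_that("block Hankel partitions follow the lag-index pattern", {
  h <- build_hankel(0:5, i = 2, j = 3)
  expect_equal(h$Yp, rbind(c(0, 1, 2), c(1, 2, 3)))
  expect_equal(h$Yf, rbind(c(2, 3, 4), c(3, 4, 5)))
  expect_equal(h$Yp_plus, rbind(c(0, 1, 2), c(1, 2, 3), c(2, 3, 4)))
  expect_equal(h$Yf_minus, rbind(c(3, 4, 5)))
  # auto j uses every sample
  h2 <- build_hankel(0:9, i = 3)
  expect_equal(h2$j, 5)
  expect_equal(h2$Yf[3, 5], 9)
})

test_that("hankel construction rejects too-short signals with an informative error", {
  expect_error(build_hankel(1:5, i = 3), "at least")
  expect_error(build_hankel(1:100, i = 1), "i")
})

test_that("constant signal yields rank-1 projected data", {
  h <- build_hankel(rep(3, 40), i = 4)
  expect_true(all(h$Yp == 3) && all(h$Yf == 3))
  Oi <- orthogonal_project(h$Yf, h$Yp)
  sv <- svd(Oi)$d
  expect_equal(sum(sv > 1e-10 * sv[1]), 1)
})

test_that("projection reproduces contained rows, annihilates orthogonal ones, and is idempotent", {
  Wp <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  inside <- rbind(c(2, 3, 0, 0), c(-1, 5, 0, 0))
  expect_equal(orthogonal_project(inside, Wp), inside)
  outside <- rbind(c(0, 0, 1, 2), c(0, 0, -3, 1))
  expect_equal(orthogonal_project(outside, Wp),
               matrix(0, 2, 4))
  set.seed(0)
  Yf <- matrix(rnorm(24), 4, 6)
  W <- matrix(rnorm(24), 4, 6)
  once <- orthogonal_project(Yf, W)
  expect_equal(orthogonal_project(once, W), once, tolerance = 1e-10)
})

test_that("projection equals the explicit normal-equations least-squares reconstruction", {
  set.seed(0)
  Yf <- matrix(rnorm(24), 4, 6)
  Wp <- matrix(rnorm(24), 4, 6)
  # oracle: argmin_G || Yf - G Wp ||_F solved row-wise by QR on t(Wp)
  G_oracle <- t(qr.solve(t(Wp), t(Yf)))
  expect_equal(orthogonal_project(Yf, Wp), G_oracle %*% Wp, tolerance = 1e-10)
  # rank-deficient Wp is handled through the pseudo-inverse, no error
  Wp_def <- rbind(Wp[1, ], Wp[1, ], Wp[2, ], Wp[3, ])
  expect_silent(orthogonal_project(Yf, Wp_def))
})

test_that("oblique projection removes the future-input contribution", {
  set.seed(1)
  Uf <- matrix(rnorm(12), 2, 6)
  Wp <- matrix(rnorm(18), 3, 6)
  # Yf built purely from Uf rows projects to (numerically) nothing along Uf
  Yf <- rbind(2 * Uf[1, ] - Uf[2, ], Uf[1, ] + 3 * Uf[2, ])
  Ob <- orthogonal_project(Yf, Wp, Uf = Uf)
  expect_lt(max(abs(Ob)), 1e-9 * max(abs(Yf)))
  expect_error(orthogonal_project(Yf, Wp[, 1:5]), "column count")
})

test_that("SVD-gap order selection follows the largest relative gap above threshold", {
  expect_identical(estimate_order(c(10, 9, 0.01, 0.005)), 2L)
  expect_identical(estimate_order(c(5, 0, 0, 0)), 1L)
  expect_warning(ord <- estimate_order(c(0, 0, 0)), "zero")
  expect_identical(ord, 0L)
  expect_error(estimate_order(c(1, 2, 3)), "non-increasing")
  # noise-free second-order data: exactly two significant singular values
  y <- ring_signal(zeta = 0.25)
  h <- build_hankel(y$samples, i = 20)
  sv <- svd(orthogonal_project(h$Yf, h$Yp))$d
  expect_identical(estimate_order(sv), 2L)
  expect_lt(sv[3] / sv[1], 1e-8)
})

test_that("n4sid recovers noise-free second-order dynamics to high precision", {
  p <- second_order_params(1e7, 0.25, gain = 1e-7)
  y <- simulate_pa_signal(p, ts = 1e-8, n_samples = 2000)
  fit <- n4sid_fit(y)
  expect_identical(fit$order, 2L)
  expect_lt(abs(fit$modal$omega_n - 1e7) / 1e7, 1e-3)
  expect_lt(abs(fit$modal$zeta - 0.25) / 0.25, 1e-3)
  expect_gt(fit$nrmse_percent, 99.9)
  expect_true(fit$stable)
  expect_equal(fit$eigenvalues,
               eigen(fit$model$A, only.values = TRUE)$values)
})

test_that("identified NRMSE and eigenvalues are invariant to amplitude scaling", {
  y <- ring_signal(zeta = 0.3, snr_db = 25, seed = 9)
  y_scaled <- pa_signal(137 * y$samples, ts = y$ts)
  f1 <- n4sid_fit(y, order = 2)
  f2 <- n4sid_fit(y_scaled, order = 2)
  expect_equal(f1$nrmse_percent, f2$nrmse_percent, tolerance = 1e-8)
  expect_equal(sort(Mod(f1$eigenvalues)), sort(Mod(f2$eigenvalues)),
               tolerance = 1e-8)
})

test_that("degenerate inputs raise no-dynamics errors", {
  expect_error(n4sid_fit(pa_signal(rep(0, 500), 1e-8)), "constant|dynamics")
  expect_error(n4sid_fit(pa_signal(rep(2.5, 500), 1e-8)), "constant|dynamics")
})

test_that("preprocessing decimates oversampled records by block averaging", {
  y <- ring_signal(fn_mhz = 2, zeta = 0.3, spp = 300, n_samples = 30000)
  pre <- preprocess_signal(y, target_spp = 30)
  expect_equal(pre$meta$decimation_factor, 10)
  expect_equal(pre$ts, y$ts * 10)
  # block means after tail-estimated DC removal
  dc <- mean(utils::tail(y$samples, 3000))
  expect_equal(pre$samples[1], mean(y$samples[1:10]) - dc, tolerance = 1e-12)
})
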