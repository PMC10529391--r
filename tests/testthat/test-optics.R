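test_that("sphere algebra follows Rcd = m Pr/Pd, Tcd = m Pt/Pd, Tc = Pcoh/Po", {
  m <- sphere_measurement(Pd = 2, Pr = 2, Pt = 1, Pcoh = 0.5, Po = 1)
  expect_equal(reflectance_cd(m), 0.98)
  expect_equal(transmittance_cd(m), 0.49)
  expect_equal(transmittance_coherent(m), 0.5)
  # linearity in Pt
  m2 <- sphere_measurement(Pd = 2, Pr = 2, Pt = 2, Pcoh = 1, Po = 1)
  expect_equal(transmittance_cd(m2), 2 * transmittance_cd(m))
  expect_equal(transmittance_coherent(m2), 1)
  zero <- sphere_measurement(Pd = 1, Pr = 0, Pt = 0, Pcoh = 0, Po = 1)
  expect_equal(reflectance_cd(zero), 0)
  expect_equal(transmittance_coherent(zero), 0)
  bad <- sphere_measurement(Pd = 0, Pr = 1, Pt = 1, Pcoh = 0, Po = 0)
  expect_error(reflectance_cd(bad), "zero")
  expect_error(transmittance_coherent(bad), "zero")
  # the power ratio needed to report Rcd = 0.44 under m = 0.98
  expect_equal(0.44 / 0.98, 0.44898, tolerance = 1e-5)
  m3 <- sphere_measurement(Pd = 1, Pr = 0.44 / 0.98, Pt = 0, Pcoh = 0, Po = 1)
  expect_equal(reflectance_cd(m3), 0.44)
})

test_that("measurement ratios are invariant to a common power scale", {
  a <- sphere_measurement(Pd = 1, Pr = 0.3, Pt = 0.4, Pcoh = 0.1, Po = 0.9)
  b <- sphere_measurement(Pd = 7, Pr = 2.1, Pt = 2.8, Pcoh = 0.7, Po = 6.3)
  expect_equal(reflectance_cd(a), reflectance_cd(b))
  expect_equal(transmittance_cd(a), transmittance_cd(b))
  expect_equal(transmittance_coherent(a), transmittance_coherent(b))
})

test_that("reduced scattering reproduces the printed panel value and limits", {
  expect_equal(round(reduced_scattering(51.82, 0.80), 2), 10.36)
  expect_equal(reduced_scattering(12, 0), 12)
  expect_equal(reduced_scattering(12, 1), 0)
  p <- optical_properties(0.05, 54.94, 0.62)
  expect_equal(p$mu_s_prime, 54.94 * 0.38)
})

test_that("Monte-Carlo slab honors the Beer-Lambert limit and conserves energy", {
  # mu_s = 0: no scattering, coherent transmission exp(-mu_a d), nothing reflected
  fw <- mc_forward_slab(optical_properties(2, 0, 0), thickness_um = 500,
                        n_photons = 2e5, seed = 1)
  se <- sqrt(exp(-0.1) * (1 - exp(-0.1)) / 2e5)
  expect_lt(abs(fw$T_coherent - exp(-0.1)), 3 * se)
  expect_equal(fw$R_diffuse, 0)
  # mu_a = 0: all photons leave, none absorbed
  fw0 <- mc_forward_slab(optical_properties(0, 50, 0.8), thickness_um = 500,
                         n_photons = 1e5, seed = 2)
  expect_equal(fw0$absorbed, 0)
  expect_equal(fw0$R_diffuse + fw0$T_diffuse + fw0$T_coherent, 1)
  # exact photon bookkeeping in the general case
  fw1 <- mc_forward_slab(optical_properties(2, 50, 0.8), thickness_um = 500,
                         n_photons = 5e4, seed = 3)
  expect_equal(fw1$R_diffuse + fw1$T_diffuse + fw1$T_coherent + fw1$absorbed, 1)
  expect_error(mc_forward_slab(optical_properties(1, 1, 0), 500, n_photons = 10),
               "n_photons")
})

test_that("a 1e5-photon run agrees with a high-photon reference of the same engine", {
  props <- optical_properties(0.5, 50, 0.8)
  ref <- mc_forward_slab(props, 100, n_photons = 2e6, seed = 10)
  run <- mc_forward_slab(props, 100, n_photons = 1e5, seed = 11)
  for (q in c("R_diffuse", "T_diffuse", "T_coherent")) {
    se <- sqrt(ref[[q]] * (1 - ref[[q]]) / 1e5)
    expect_lt(abs(run[[q]] - ref[[q]]), 3 * se + 1e-12)
  }
})

test_that("the coherent-only inverse is the exact Beer-Lambert inverse", {
  inv <- invert_optical_props(0, 0, Tc = 0.2, thickness_um = 500, fix_mu_s = 0)
  expect_equal(inv$props$mu_a, -log(0.2) / 0.05, tolerance = 1e-12)
  expect_identical(inv$flag, "ok")
})

test_that("a black sample is flagged as diverging absorption", {
  inv <- invert_optical_props(0, 0, 0, thickness_um = 100)
  expect_identical(inv$flag, "diverging-absorption")
  expect_null(inv$props)
})

test_that("the inversion is deterministic for a fixed seed", {
  obs <- c(0.13, 0.66, 0.074)
  a <- invert_optical_props(obs[1], obs[2], obs[3], 500, n_photons = 2e4,
                            seed = 5, max_iter = 40)
  b <- invert_optical_props(obs[1], obs[2], obs[3], 500, n_photons = 2e4,
                            seed = 5, max_iter = 40)
  expect_identical(a$props$mu_a, b$props$mu_a)
  expect_identical(a$residual, b$residual)
})

test_that("fixing g reduces the fit to (mu_a, mu_s) for two-observable panels", {
  truth <- optical_properties(2, 50, 0.8)
  obs <- mc_forward_slab(truth, 500, n_photons = 5e5, seed = 6)
  inv <- invert_optical_props(obs$R_diffuse, obs$T_diffuse, obs$T_coherent,
                              500, fix_g = 0.8, n_photons = 5e4, seed = 7,
                              max_iter = 120)
  expect_equal(inv$props$g, 0.8)
  expect_lt(abs(inv$props$mu_s - 50) / 50, 0.1)
})

test_that("sphere measurement reader round-trips a small table", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = c("a", "b"), Pd = c(1, 2), Pr = c(0.4, 0.5),
                       Pt = c(0.5, 0.6), Pcoh = c(0, 0.1), Po = c(1, 1),
                       thickness_um = c(100, 100)),
            path, row.names = FALSE)
  ms <- read_sphere_measurements(path)
  expect_named(ms, c("a", "b"))
  expect_equal(reflectance_cd(ms$a), 0.98 * 0.4)
  expect_error(read_sphere_measurements(tempfile_with <- {
    p2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(sample_id = "a", Pd = 1), p2, row.names = FALSE)
    p2
  }), "missing columns")
})
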