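test_that("photon flux converts to irradiance through N_A h c / lambda", {
  expect_equal(photon_constants()$N_A_h_c, 0.1196266, tolerance = 1e-6)
  expect_equal(photon_to_energy(1.6e-5, 350), 5.4686, tolerance = 1e-4)
  expect_equal(signif(photon_to_energy(1.6e-5, 350), 2), 5.5)
  expect_equal(signif(photon_to_energy(18, 445), 2), 4.8e6)
  expect_equal(photon_to_energy(0, 550), 0)
  expect_error(photon_to_energy(1, -5), "positive")
})

test_that("energy/photon round trip is exact and follows the 1/lambda law", {
  for (lam in seq(300, 800, 50)) {
    x <- 3.7e-4
    expect_equal(energy_to_photon(photon_to_energy(x, lam), lam), x,
                 tolerance = 1e-12)
  }
  expect_equal(energy_to_photon(5.4686, 350), 1.6e-5, tolerance = 1e-4)
  # at fixed power, photon flux increases with wavelength
  flux <- energy_to_photon(10, seq(300, 800, 100))
  expect_true(all(diff(flux) > 0))
})

test_that("tabulated energy-unit bounds match the photon bounds at printed precision", {
  cells <- table1_w_cells()
  for (k in seq_len(nrow(cells))) {
    rec <- load_actinometer(cells$name[k])
    e <- rec$entries[rec$entries$lambda_exc_nm == cells$lambda[k], ]
    flux <- if (cells$bound[k] == "upper") e$i_max else e$i_min
    w <- photon_to_energy(flux, cells$lambda[k])
    expect_lte(abs(w - cells$printed_w[k]), cells$unit[k],
               label = sprintf("%s %g nm %s bound (%g W m-2 vs printed %g)",
                               cells$name[k], cells$lambda[k], cells$bound[k],
                               w, cells$printed_w[k]))
  }
})

test_that("two-wavelength intensity transfer inverts its forward model", {
  expect_equal(transfer_intensity(F1 = 1, F2 = 1, I1 = 5, eps1 = 1, eps2 = 1), 5)
  expect_equal(transfer_intensity(F1 = 1, F2 = 2, I1 = 5, eps1 = 1, eps2 = 1), 10)
  # forward-generate F_i = k * I_i * eps(lambda_i), invert exactly
  set.seed(3)
  for (r in 1:10) {
    k <- runif(1, 0.1, 10); I1 <- runif(1, 1e-4, 10); I2 <- runif(1, 1e-4, 10)
    e1 <- runif(1, 0.2, 1); e2 <- runif(1, 0.2, 1)
    F1 <- k * I1 * e1; F2 <- k * I2 * e2
    expect_equal(transfer_intensity(F1, F2, I1, e1, e2), I2, tolerance = 1e-12)
  }
  # invariance under common rescaling of the F's and of the eps's
  expect_equal(transfer_intensity(3 * 1, 3 * 2, 5, 0.4 * 1, 0.4 * 0.5),
               transfer_intensity(1, 2, 5, 1, 0.5), tolerance = 1e-12)
  expect_error(transfer_intensity(0, 1, 5, 1, 1), "positive")
})

test_that("action spectra are overlap products with the right integrals", {
  resp <- load_spectrum(data.frame(nm = seq(400, 700, 5),
                                   v = exp(-((seq(400, 700, 5) - 550) / 70)^2)),
                        kind = "normalized_excitation")
  # near-delta source: integral of the action spectrum sifts the response
  delta <- simulate_source_spectrum(data.frame(center_nm = 550, fwhm_nm = 1.5,
                                               weight = 1))
  a <- action_spectrum(delta, resp)
  expect_equal(integrate_spectrum(a), spectrum_value_at(resp, 550),
               tolerance = 0.01)
  # flat response: unit-integral source integrates to 1
  flat <- load_spectrum(data.frame(nm = c(300, 900), v = c(1, 1)),
                        kind = "normalized_excitation")
  src <- simulate_source_spectrum(data.frame(center_nm = 500, fwhm_nm = 40,
                                             weight = 1))
  expect_equal(integrate_spectrum(action_spectrum(src, flat)), 1,
               tolerance = 1e-6)
  # triangle x triangle against a near-exact fine-grid quadrature
  tri1 <- load_spectrum(data.frame(nm = c(400, 500, 600), v = c(0, 1, 0)),
                        kind = "source_emission", normalization = "unit_integral")
  tri2 <- load_spectrum(data.frame(nm = c(450, 550, 650), v = c(0, 1, 0)),
                        kind = "normalized_excitation")
  g <- seq(450, 600, 0.01)
  f1 <- approx(tri1$wavelength_nm, tri1$value, g)$y
  f2 <- approx(tri2$wavelength_nm, tri2$value, g)$y
  oracle <- pracma::trapz(g, f1 * f2)
  expect_equal(integrate_spectrum(action_spectrum(tri1, tri2)), oracle,
               tolerance = 1e-4)
  expect_error(action_spectrum(tri1,
                               load_spectrum(data.frame(nm = c(700, 800),
                                                        v = c(1, 1)),
                                             kind = "normalized_excitation")),
               "overlap")
})

test_that("the effective cross section reduces to sigma(lambda0) for narrow sources", {
  grid <- seq(400, 560, 2)
  sig <- load_spectrum(data.frame(nm = grid,
                                  v = 198 * exp(-((grid - 480) / 60)^2)),
                       kind = "cross_section")
  # constant sigma: sigma_eff equals it for any source inside the support
  flat_sig <- load_spectrum(data.frame(nm = c(350, 700), v = c(198, 198)),
                            kind = "cross_section")
  src <- simulate_source_spectrum(data.frame(center_nm = 480, fwhm_nm = 30,
                                             weight = 1))
  expect_equal(effective_sigma(flat_sig, src), 198, tolerance = 1e-6)
  # narrow source limit
  narrow <- simulate_source_spectrum(data.frame(center_nm = 480, fwhm_nm = 2,
                                                weight = 1))
  expect_equal(effective_sigma(sig, narrow), 198, tolerance = 0.01)
  # end-to-end: tau measured under the source gives back S_I
  S_I <- 2.5e-3
  s_eff <- effective_sigma(sig, src)
  tau <- 1 / (s_eff * S_I)
  expect_equal(tau_to_intensity(tau, s_eff), S_I, tolerance = 1e-12)
})

test_that("polychromatic transfer recovers the integral photon flux", {
  white <- simulate_source_spectrum(data.frame(center_nm = c(450, 550),
                                               fwhm_nm = c(20, 100),
                                               weight = c(1, 1.6)))
  grid <- seq(380, 700, 2)
  eps <- load_spectrum(data.frame(nm = grid,
                                  v = exp(-((grid - 470) / 80)^2)),
                       kind = "normalized_excitation",
                       normalization = "unit_at_reference", lambda_ref = 470)
  overlap <- integrate_spectrum(action_spectrum(white, eps))
  # forward model: F_target / F_ref = S_I * overlap / (I_ref * eps(470))
  S_true <- 1.4e-3; I_ref <- 2e-3
  F_ratio <- S_true * overlap / I_ref
  res <- polychromatic_transfer(F_ratio, I_ref, eps, white)
  expect_equal(res$S_I, S_true, tolerance = 1e-9)
  expect_equal(integrate_spectrum(res$I_lambda), S_true, tolerance = 1e-6)
  # linearity
  expect_equal(polychromatic_transfer(2 * F_ratio, I_ref, eps, white)$S_I,
               2 * S_true, tolerance = 1e-9)
  # narrow source at the reference wavelength reduces to the two-point transfer
  line <- simulate_source_spectrum(data.frame(center_nm = 470, fwhm_nm = 1.5,
                                              weight = 1))
  red <- polychromatic_transfer(0.8, I_ref, eps, line)
  expect_equal(red$S_I, 0.8 * I_ref, tolerance = 0.01)
  # band-aware reference mode matches the monochromatic default for a
  # narrow reference
  band <- polychromatic_transfer(F_ratio, I_ref, eps, white, ref_source = line)
  expect_equal(band$S_I, res$S_I, tolerance = 0.01)
  expect_error(polychromatic_transfer(1, 1, white, white), "unit_at_reference")
})
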