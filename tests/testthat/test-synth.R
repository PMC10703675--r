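test_that("simulated monoexponential kinetics match the closed form", {
  # t = 0 returns F0
  ts <- simulate_timeseries(tau = 0.63, F0 = 1, F_inf = 0.2, times = c(0, 1, 2, 3))
  expect_equal(ts$fluorescence[1], 1)
  # unit decay
  ts <- simulate_timeseries(tau = 1, F0 = 1, F_inf = 0, times = c(0, 1, 2, 3))
  expect_equal(ts$fluorescence[2], exp(-1), tolerance = 1e-12)
  # rise curve reaches half amplitude at tau * ln 2
  ts <- simulate_timeseries(tau = 2, F0 = 0, F_inf = 1,
                            times = c(0, 2 * log(2), 5, 10))
  expect_equal(ts$fluorescence[2], 0.5, tolerance = 1e-12)

  expect_error(simulate_timeseries(1, 1, 0, numeric(0)), "empty")
  expect_error(simulate_timeseries(-1, 1, 0, 0:4), "positive")
  expect_error(simulate_timeseries(1, 1, 1, 0:4), "differ")
  expect_error(simulate_timeseries(1, 1, 0, c(0, 2, 1, 3)), "increasing")
})

test_that("noise realizations are seed-reproducible and leave the RNG alone", {
  nm <- noise_model("gaussian_additive", 0.05, seed = 42)
  t <- seq(0, 5, 0.1)
  a <- simulate_timeseries(1, 1, 0, t, nm)
  b <- simulate_timeseries(1, 1, 0, t, nm)
  expect_identical(a$fluorescence, b$fluorescence)
  c2 <- simulate_timeseries(1, 1, 0, t, noise_model("gaussian_additive", 0.05, seed = 43))
  expect_false(identical(a$fluorescence, c2$fluorescence))

  set.seed(7); before <- .Random.seed
  simulate_timeseries(1, 1, 0, t, nm)
  expect_identical(.Random.seed, before)

  sh <- simulate_timeseries(1, 1, 0, t, noise_model("shot_like", 0.02, seed = 1))
  expect_identical(sh$fluorescence,
                   simulate_timeseries(1, 1, 0, t, noise_model("shot_like", 0.02, seed = 1))$fluorescence)
})

test_that("noiseless simulate -> fit round trip recovers tau over 9 decades", {
  for (tau in 10^seq(-6, 3, by = 1.5)) {
    ts <- simulate_timeseries(tau, F0 = 1, F_inf = 0.1,
                              times = seq(0, 5 * tau, length.out = 60))
    fit <- fit_monoexp(ts)
    expect_lt(abs(fit$tau - tau) / tau, 1e-3)
  }
})

test_that("inner-filter forward model has the right limits and bias decay", {
  t <- seq(0, 60, 0.2)
  # no photochemistry: constant reporter signal
  const <- simulate_inner_filter_series(A0 = 0.1, A_inf = 0.1, tau = 10,
                                        reporter_level = 3, times = t)
  expect_equal(diff(range(const$fluorescence)), 0)
  # zero-absorbance limit: attenuation factor -> 1
  tiny <- simulate_inner_filter_series(A0 = 1e-9, A_inf = 0, tau = 10,
                                       reporter_level = 3, times = t)
  expect_equal(tiny$fluorescence, rep(3, length(t)), tolerance = 1e-8)
  expect_error(simulate_inner_filter_series(A0 = 0.05, A_inf = 0.1, tau = 10,
                                            times = t), "A_inf")
  expect_warning(simulate_inner_filter_series(A0 = 0.2, A_inf = 0, tau = 10,
                                              times = t), "0.15")
  expect_error(simulate_inner_filter_series(A0 = 0.4, A_inf = 0, tau = 10,
                                            times = t), "0.3")

  # the nonlinearity of the attenuation biases the fitted tau; the bias
  # shrinks monotonically with the working absorbance
  devs <- vapply(c(0.15, 0.05, 0.01), function(A0) {
    s <- simulate_inner_filter_series(A0 = A0, A_inf = 0, tau = 10, times = t)
    abs(fit_monoexp(s)$tau - 10) / 10
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[1], 0.07)
  expect_lt(devs[3], 0.005)
})

test_that("photosynthetic rise follows the two-exponential model", {
  t <- seq(0, 5e-4, 2e-6)
  ts <- simulate_pa_rise(I = 1e-2, amplitudes = c(0.2, 0.6, 0.2), times = t)
  expect_equal(ts$fluorescence[1], 0.2)
  # A2 = 0 reduces to a monoexponential rise with rate sigma_pa * I
  k1 <- 2.0e6 * 1e-2   # 2e4 1/s
  mono <- simulate_pa_rise(I = 1e-2, amplitudes = c(0.2, 0.8, 0), times = t)
  ref <- simulate_timeseries(tau = 1 / k1, F0 = 0.2, F_inf = 1, times = t)
  expect_equal(mono$fluorescence, ref$fluorescence, tolerance = 1e-12)

  expect_error(simulate_pa_rise(I = 1, times = t), "reliable range")
  expect_error(simulate_pa_rise(I = 1e-2, slow_ratio = 0.5, times = t),
               "separable")
})

test_that("illumination fields are deterministic with recorded ground truth", {
  u <- make_intensity_field("uniform", c(5, 5), I = 1)
  expect_equal(u$intensity, matrix(1, 5, 5))

  g <- make_intensity_field("linear_gradient", c(32, 32), I = 5,
                            angle_deg = 3, rel_slope = 0.01)
  expect_equal(g$params$angle_deg, 3)
  expect_true(all(g$intensity > 0))

  sp <- make_intensity_field("gaussian_spot", c(33, 33), I = 7, sd_px = 5)
  expect_equal(which(sp$intensity == max(sp$intensity), arr.ind = TRUE)[1, ],
               c(row = 17, col = 17))

  expect_error(make_intensity_field("linear_gradient", c(64, 64), I = 1,
                                    rel_slope = 1), "negative")
})

test_that("simulated source spectra are unit-integral band sums", {
  one <- simulate_source_spectrum(data.frame(center_nm = 500, fwhm_nm = 10,
                                             weight = 1))
  expect_equal(integrate_spectrum(one), 1, tolerance = 1e-9)
  expect_equal(one$wavelength_nm[which.max(one$value)], 500)

  two <- simulate_source_spectrum(data.frame(center_nm = c(450, 550),
                                             fwhm_nm = c(10, 10),
                                             weight = c(1, 1)))
  half <- two$wavelength_nm <= 500
  expect_equal(pracma::trapz(two$wavelength_nm[half], two$value[half]), 0.5,
               tolerance = 1e-6)

  white <- simulate_source_spectrum(data.frame(center_nm = c(450, 550),
                                               fwhm_nm = c(20, 100),
                                               weight = c(1, 1.6)))
  expect_equal(integrate_spectrum(white), 1, tolerance = 1e-9)
  expect_error(simulate_source_spectrum(data.frame(center_nm = 500,
                                                   fwhm_nm = -1, weight = 1)),
               "positive")
})

test_that("stack simulation reduces to 0-D kinetics at D = 0", {
  # uniform field: every pixel follows the closed-form time series
  fld <- make_intensity_field("uniform", c(8, 8), I = 5)
  tmg <- timing_model("widefield", frame_interval = 2e-4)
  st <- simulate_stack(fld, sigma = 198, n_frames = 20, timing = tmg)
  ref <- simulate_timeseries(1 / (198 * 5), 1, 0, frames_to_times(20, tmg))
  for (px in list(c(1, 1), c(4, 7), c(8, 8))) {
    expect_equal(st$frames[px[1], px[2], ], ref$fluorescence,
                 tolerance = 1e-9)
  }
  # two-level step field: per-pixel tau map reproduces the step exactly
  step <- make_intensity_field("disk_array", c(16, 16), I = 5, I_out = 1,
                               radius_px = 4, spacing_px = 16)
  st2 <- simulate_stack(step, sigma = 198, n_frames = 30, timing = tmg)
  tm <- fit_stack(st2)
  taus <- sort(unique(round(tm$tau[tm$mask], 12)))
  expect_equal(length(taus), 2L)
  expect_equal(taus[2] / taus[1], 5, tolerance = 1e-6)  # tau ratio = inverse I ratio
})

test_that("diffusion conserves mass with no reaction and no-flux walls", {
  fld <- make_intensity_field("disk_array", c(24, 24), I = 5, I_out = 0.5,
                              radius_px = 5, spacing_px = 12,
                              pixel_size = 1e-6)
  # dt = dx^2/(4D) = 2.5e-4 s; 4 frames at 0.0625 s span 1000 steps
  st <- simulate_stack(fld, sigma = 0, n_frames = 5,
                       timing = timing_model("widefield", frame_interval = 0.0625),
                       D = 1e-9)
  tot <- apply(st$frames, 3, sum)
  expect_lt(max(abs(tot / tot[1] - 1)), 1e-9)
})

test_that("diffusion blurs the retrieved pattern while preserving the mean", {
  fld <- make_intensity_field("disk_array", c(32, 32), I = 5, I_out = 0.5,
                              radius_px = 5, spacing_px = 16,
                              pixel_size = 1e-6)
  tmg <- timing_model("widefield", frame_interval = 2.5e-4)
  m0 <- map_intensity(fit_stack(simulate_stack(fld, 198, n_frames = 30,
                                               timing = tmg, D = 0)),
                      load_actinometer("Dronpa-2"), 480)
  mD <- map_intensity(fit_stack(simulate_stack(fld, 198, n_frames = 30,
                                               timing = tmg, D = 2e-9)),
                      load_actinometer("Dronpa-2"), 480)
  expect_lt(abs(mD$stats$mean / m0$stats$mean - 1), 0.05)
  expect_lt(sd(mD$intensity[mD$mask]), sd(m0$intensity[m0$mask]))
})

test_that("identical noise seeds give bit-identical stacks", {
  fld <- make_intensity_field("uniform", c(6, 6), I = 5)
  tmg <- timing_model("widefield", frame_interval = 2e-4)
  nm <- noise_model("gaussian_additive", 0.02, seed = 9)
  a <- simulate_stack(fld, 198, n_frames = 10, timing = tmg, noise = nm)
  b <- simulate_stack(fld, 198, n_frames = 10, timing = tmg, noise = nm)
  expect_identical(a$frames, b$frames)
})

test_that("an unattainable diffusion step budget errors with grid advice", {
  fld <- make_intensity_field("uniform", c(16, 16), I = 5, pixel_size = 1e-8)
  expect_error(
    simulate_stack(fld, 198, n_frames = 10,
                   timing = timing_model("widefield", frame_interval = 1),
                   D = 1e-9, max_steps = 1e4),
    "coarser grid")
})
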