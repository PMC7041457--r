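test_that("noiseless truth is recovered exactly", {
  for (sym in c(TRUE, FALSE)) {
    f <- fit_brillouin(default_truth, symmetric_pair = sym)
    expect_true(f$success)
    expect_equal(f$shift_ghz, 10, tolerance = 1e-6)
    expect_equal(f$linewidth_ghz, 1, tolerance = 1e-6)
    expect_equal(f$amplitude, 1000, tolerance = 1e-3)
    expect_lt(f$rms_error_pct, 1e-6)
  }
})

test_that("finely sampled spectra recover parameters to high precision", {
  m <- spectrometer_model(n_pixels = 4096, bandwidth_ghz = 60,
                          pixel_pitch_um = 6.5)
  pk <- peak_set(brillouin_shift_ghz = 7.3, brillouin_fwhm_ghz = 1.4,
                 brillouin_amplitude = 812, rayleigh_amplitude = 0.0)
  s <- synth_truth(pk, m)
  s$meta$peaks <- NULL                       # no hints for the fit
  f <- fit_brillouin(s, include_rayleigh = FALSE)
  expect_equal(f$shift_ghz, 7.3, tolerance = 1e-6)
  expect_equal(f$linewidth_ghz, 1.4, tolerance = 1e-6)
  expect_equal(f$amplitude, 812, tolerance = 812 * 1e-6)
})

test_that("default initial guesses start near the truth", {
  init <- default_init(default_truth)
  expect_false(init$fallback)
  expect_lt(abs(init$shift_ghz - 10), 0.5)   # within one pixel
  flat <- brillouin_spectrum(default_model$frequency_ghz, rep(3, 120))
  expect_warning(fb <- default_init(flat), "fallback|candidates")
  expect_true(fb$fallback)
})

test_that("initial guesses stay close to the truth across noise realisations", {
  good <- 0
  for (i in 1:100) {
    init <- default_init(noisy_spectrum(10, 300 + i))
    if (abs(init$shift_ghz - 10) <= 1.5) good <- good + 1   # 3 pixels
  }
  expect_gte(good, 95)
})

test_that("the shift estimate is invariant to intensity rescaling", {
  s <- noisy_spectrum(10, 17)
  s2 <- s; s2$intensity <- 13 * s$intensity
  f1 <- fit_brillouin(s)
  f2 <- fit_brillouin(s2)
  expect_equal(f2$shift_ghz, f1$shift_ghz, tolerance = 1e-6)
  expect_equal(f2$amplitude, 13 * f1$amplitude, tolerance = 1e-4)
})

test_that("reported RMS error matches recomputation from residuals", {
  s <- noisy_spectrum(5, 23)
  f <- fit_brillouin(s)
  rms <- sqrt(mean((predict(f)[s$mask] - s$intensity[s$mask])^2))
  expect_equal(f$rms_error_pct, rms / abs(f$amplitude) * 100,
               tolerance = 1e-10)
})

test_that("fit methods expose the standard modelling interface", {
  f <- fit_brillouin(noisy_spectrum(10, 29))
  expect_named(coef(f), c("shift_ghz", "fwhm_ghz", "amplitude",
                          "rayleigh_amplitude", "rayleigh_fwhm"))
  expect_length(fitted(f), 120)
  expect_length(residuals(f), 120)
  expect_equal(predict(f), fitted(f))
  expect_equal(dim(vcov(f)), c(5, 5))
  expect_output(print(f), "shift")
  expect_output(summary(f), "std_error")
  p <- predict(f, newdata = c(-10, 10))
  expect_length(p, 2)
  expect_equal(p[1], p[2], tolerance = 1e-6)     # symmetric model
})

test_that("masking the centre drops the Rayleigh component", {
  s <- mask_range(noisy_spectrum(10, 31), -3, 3)
  f <- fit_brillouin(s)
  expect_null(f$rayleigh)
  expect_true(f$success)
  expect_equal(f$shift_ghz, 10, tolerance = 0.2)
})

test_that("degenerate inputs error or flag failure rather than crash", {
  expect_error(fit_brillouin(structure(list(frequency_ghz = rep(1, 5)),
                                       class = "brillouin_spectrum")),
               "degenerate|axis")
  short <- brillouin_spectrum(seq(0, 3.5, 0.5), rep(1, 8))
  expect_error(suppressWarnings(fit_brillouin(short)), "too few")
})

test_that("speed of sound conversion is the standard closed form", {
  v <- speed_of_sound(10, 561, 1.33, 180)
  expect_equal(speed_of_sound(20, 561, 1.33, 180), 2 * v)      # linear in shift
  # water-like round trip: ~1490 m/s at 561 nm corresponds to ~7.07 GHz
  om <- brillouin_shift_for_speed(1490, 561, 1.33, 180)
  expect_equal(om, 7.065, tolerance = 1e-3)
  expect_equal(speed_of_sound(om, 561, 1.33, 180), 1490, tolerance = 1e-9)
  # v scales as 1/sin(theta/2): halving the sine doubles the speed
  expect_equal(speed_of_sound(om, 561, 1.33, 60),
               2 * speed_of_sound(om, 561, 1.33, 180), tolerance = 1e-12)
  expect_error(speed_of_sound(10, 561, 1.33, 0), "angle")
  expect_error(speed_of_sound(10, 561, 0.9, 180), "refractive")
})
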