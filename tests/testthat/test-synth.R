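test_that("lorentzian line shape has the defining properties", {
  expect_equal(lorentzian(3, 3, 2, 7), 7)               # peak value
  expect_equal(lorentzian(3 + 1, 3, 2, 7), 3.5)         # half max at +FWHM/2
  expect_equal(lorentzian(3 - 1, 3, 2, 7), 3.5)
})

test_that("ground truth reproduces the simulated three-peak spectrum", {
  s <- default_truth
  expect_equal(max(s$intensity), 1e4, tolerance = 1e-2)
  expect_equal(s$frequency_ghz[which.max(s$intensity)], 0)
  # Brillouin peaks: amplitude ~1e3 above the Rayleigh tail at +-10 GHz
  i_plus <- which(s$frequency_ghz == 10)
  expect_gt(s$intensity[i_plus], 1000)
  expect_lt(s$intensity[i_plus], 1100)
  expect_true(all(s$mask))
  expect_equal(unique(s$sigma), 0)
})

test_that("zero amplitudes give a zero spectrum", {
  pk <- peak_set(brillouin_amplitude = 0, rayleigh_amplitude = 0)
  expect_equal(synth_truth(pk, default_model)$intensity, rep(0, 120))
})

test_that("peaks outside the axis are truncated with a warning", {
  pk <- peak_set(brillouin_shift_ghz = 50)
  expect_warning(synth_truth(pk, default_model), "outside")
})

test_that("pixel-integrated sampling agrees with centre sampling for wide peaks", {
  pk <- peak_set(brillouin_fwhm_ghz = 8, rayleigh_fwhm_ghz = 8)
  a <- synth_truth(pk, default_model)$intensity
  b <- synth_truth(pk, default_model, pixel_integrated = TRUE)$intensity
  expect_equal(b, a, tolerance = 1e-3)
})

test_that("noise respects the SNR definition", {
  # sigma = brillouin amplitude / snr; at snr = 1 that is 1e3 counts
  s <- add_noise(default_truth, snr = 1, seed = 42)
  expect_equal(unique(s$sigma), 1000)
  expect_equal(sd(s$intensity - default_truth$intensity), 1000,
               tolerance = 0.05 * 3)   # 120-pixel sample estimate
  expect_equal(s$meta$snr, 1)
  r <- add_noise(default_truth, snr = 1, seed = 42, reference = "rayleigh")
  expect_equal(unique(r$sigma), 1e4)
})

test_that("sampled noise sd matches sigma over many pixels", {
  big <- spectrometer_model(n_pixels = 2000, bandwidth_ghz = 1000)
  truth <- suppressWarnings(synth_truth(default_peaks, big))
  s <- add_noise(truth, snr = 1, seed = 9)
  expect_equal(sd(s$intensity - truth$intensity), 1000, tolerance = 0.05)
})

test_that("noise generation is deterministic and leaves the RNG alone", {
  a <- add_noise(default_truth, 5, seed = 11)
  b <- add_noise(default_truth, 5, seed = 11)
  expect_identical(a$intensity, b$intensity)
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(add_noise(default_truth, 5, seed = 99))
  expect_identical(runif(1), before)
  expect_identical(add_noise(default_truth, Inf, seed = 1)$intensity,
                   default_truth$intensity)
  expect_error(add_noise(default_truth, -2, seed = 1), "positive")
})

test_that("distinct seeds give essentially independent realisations", {
  set.seed(1)
  seeds <- matrix(sample.int(1e6, 80), ncol = 2)
  r <- apply(seeds, 1, function(s) {
    a <- add_noise(default_truth, 1, s[1])$intensity - default_truth$intensity
    b <- add_noise(default_truth, 1, s[2])$intensity - default_truth$intensity
    cor(a, b)
  })
  expect_gte(mean(abs(r) < 0.3), 0.95)
})

test_that("the ensemble mean converges to the truth like sigma/sqrt(M)", {
  m <- 64
  acc <- Reduce(`+`, lapply(1:m, function(i)
    add_noise(default_truth, 1, 7000 + i)$intensity)) / m
  expect_lt(max(abs(acc - default_truth$intensity)), 1000 / sqrt(m) * 4)
})
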