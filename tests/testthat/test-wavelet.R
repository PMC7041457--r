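# Reference coefficient values in the first two blocks were computed with
# an independent DWT implementation (PyWavelets, 'symmetric' mode) on the
# same inputs and frozen here.

test_that("db2 decomposition matches the reference implementation", {
  x <- 1:10
  d <- wavedec(x, "db2", levels = 1)
  expect_equal(d$coeffs[[1]],
               c(1.76776695296637, 2.31078903454115, 5.13921615928734,
                 7.96764328403353, 10.7960704087797, 13.7885822331377),
               tolerance = 1e-14)
  expect_equal(d$coeffs[[2]],
               c(-0.612372435695794, 0, 0, 0, 0, 0.612372435695795),
               tolerance = 1e-13)
})

test_that("sym8 analysis step matches the reference implementation", {
  y <- sin(0.3 * (1:40)) * 10 + (1:40) * 0.2
  st <- dwt_step(y, wavelet_filter("sym8"))
  expect_length(st$cA, 27)
  expect_equal(st$cA[1:5],
               c(15.326605712036, 14.8161885450919, 8.20458781034212,
                 4.78678489321446, 11.6612003971468), tolerance = 1e-14)
  expect_equal(st$cD[1:5],
               c(-0.0185841615689472, 0.109891025689479, -0.25345136647706,
                 0.688920466454407, -0.71015521287776), tolerance = 1e-14)
})

test_that("multi-level transforms reconstruct perfectly", {
  set.seed(3)
  for (w in c("haar", "db2", "db4", "sym8")) {
    for (n in c(57, 120)) {
      x <- rnorm(n)
      d <- wavedec(x, w, levels = min(3, max_dwt_level(n, wavelet_filter(w)$length)))
      expect_lt(max(abs(waverec(d) - x)) / max(abs(x)), 1e-9)
    }
  }
})

test_that("orthonormal filters satisfy the quadrature-mirror relations", {
  for (w in c("haar", "db2", "db4", "sym8")) {
    filt <- wavelet_filter(w)
    expect_equal(sum(filt$dec_lo^2), 1, tolerance = 1e-12)
    expect_equal(sum(filt$dec_lo * filt$dec_hi), 0, tolerance = 1e-12)
    expect_equal(sum(filt$dec_lo), sqrt(2), tolerance = 1e-12)
  }
  expect_error(wavelet_filter("coif17"), "unknown wavelet")
})

test_that("the MAD noise estimate recovers a known sigma", {
  hits <- 0
  for (i in 1:40) {
    set.seed(500 + i)
    d <- wavedec(rnorm(1024), "sym8")
    s <- estimate_noise(d)
    if (s > 0.9 && s < 1.1) hits <- hits + 1
  }
  expect_gte(hits, 36)                       # >= 90% of seeds in [0.9, 1.1]
  expect_equal(estimate_noise(wavedec(rep(0, 64), "db2", 1)), 0)
  smooth <- estimate_noise(wavedec(default_truth$intensity))
  expect_lt(smooth, 0.01 * max(default_truth$intensity))
})

test_that("the universal threshold follows the closed form", {
  expect_equal(universal_threshold(1, 1), 0)
  expect_equal(universal_threshold(0, 1000), 0)
  expect_equal(universal_threshold(1, 120), sqrt(2 * log(120)))
  expect_equal(universal_threshold(1, 120), 3.094347, tolerance = 1e-6)
  expect_equal(universal_threshold(1, 120, dialect = "literal"),
               2 * log(120) / 120)
  expect_error(universal_threshold(1, 0), "n_samples")
  expect_error(universal_threshold(-1, 10), "noise_level")
})

test_that("soft and hard thresholding act elementwise", {
  expect_equal(soft_threshold(c(3, -3), 1), c(2, -2))
  expect_identical(soft_threshold(c(0.5, -0.3), 1), c(0, 0))
  x <- rnorm(100)
  expect_equal(soft_threshold(x, 0), x)
  expect_equal(soft_threshold(c(3, -3, 0.5), 1, soft = FALSE), c(3, -3, 0))
  expect_error(soft_threshold(1, -0.1), "threshold")
})

test_that("denoising energy never exceeds the input energy", {
  for (seed in 1:5) {
    s <- noisy_spectrum(3, seed)
    out <- wa_denoise(s)
    expect_lte(sum(out$intensity^2), sum(s$intensity^2) * (1 + 1e-12))
  }
})

test_that("a zero manual threshold reproduces the input", {
  s <- noisy_spectrum(5, 2)
  out <- wa_denoise(s, rule = "manual", threshold = 0)
  expect_lt(max(abs(out$intensity - s$intensity)) / max(abs(s$intensity)),
            1e-9)
  expect_error(wa_denoise(s, rule = "manual"), "threshold")
})

test_that("denoising is linear in a joint rescaling of data and noise", {
  s <- noisy_spectrum(5, 4)
  k <- 42
  s2 <- s; s2$intensity <- k * s$intensity
  a <- wa_denoise(s, rule = "universal", noise_level = 200)
  b <- wa_denoise(s2, rule = "universal", noise_level = 200 * k)
  expect_equal(b$intensity, k * a$intensity, tolerance = 1e-9)
})

test_that("repeated shrinkage contracts less than a double threshold", {
  s <- noisy_spectrum(5, 6)
  once <- wa_denoise(s, rule = "manual", threshold = 300)
  twice <- wa_denoise(once, rule = "manual", threshold = 300)
  hard <- wa_denoise(s, rule = "manual", threshold = 600)
  expect_lte(sum((twice$intensity - once$intensity)^2),
             sum((hard$intensity - s$intensity)^2))
})

test_that("over-deep level requests are reduced with a warning", {
  s <- noisy_spectrum(5, 1)
  expect_warning(out <- wa_denoise(s, levels = 6), "too short")
  expect_length(out$intensity, 120)
  expect_warning(wavedec(rnorm(40), "sym8", levels = 3), "too short")
})

test_that("per-level thresholding runs and returns one threshold per level", {
  s <- noisy_spectrum(5, 9)
  out <- wa_denoise(s, rule = "universal_per_level")
  expect_length(out$meta$wa_threshold, 3)    # default depth for N = 120
  expect_true(all(out$meta$wa_threshold > 0))
})
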