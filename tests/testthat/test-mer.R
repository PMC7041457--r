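test_that("entropy matches hand-computed values", {
  expect_equal(shannon_entropy(rep(2, 4)), log(4))          # uniform: log N
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)           # one-hot
  expect_equal(shannon_entropy(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))    # 1.0397...
  expect_equal(shannon_entropy(c(2, 1, 1)), 1.0397208, tolerance = 1e-6)
  # relative entropy is 0 at the prior and negative elsewhere
  m <- c(4, 2, 1, 1)
  expect_equal(shannon_entropy(2 * m, prior = m), 0)
  expect_lt(shannon_entropy(c(1, 1, 1, 1), prior = m), 0)
  expect_error(shannon_entropy(c(1, -1)), "non-negative")
})

test_that("chi-squared agrees with a brute-force double loop", {
  n <- 6
  set.seed(7)
  freq <- seq(0, by = 0.5, length.out = n)
  d <- rnorm(n, 10, 2)
  sigma <- runif(n, 0.5, 2)
  s <- brillouin_spectrum(freq, d, sigma = sigma)
  f <- rnorm(n, 10, 2)
  expect_equal(chi_squared(f, s), chi_squared_loops(f, d, sigma),
               tolerance = 1e-12)
  # with an instrument response and a mask
  m <- spectrometer_model(n_pixels = n, bandwidth_ghz = n / 2,
                          response_fwhm_ghz = 1)
  s2 <- brillouin_spectrum(m$frequency_ghz, d, sigma = sigma,
                           mask = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(chi_squared(f, s2, m),
               chi_squared_loops(f, d, sigma, m$response, s2$mask),
               tolerance = 1e-12)
})

test_that("chi-squared endpoints behave as expected", {
  s <- noisy_spectrum(5)
  expect_equal(chi_squared(s$intensity, s), 0)
  expect_equal(chi_squared(s$intensity + s$sigma, s), 1)
  s$mask[] <- FALSE
  expect_error(chi_squared(s$intensity, s), "masked")
})

test_that("analytic gradients match central finite differences", {
  n <- 8
  set.seed(21)
  s <- brillouin_spectrum(seq(0, by = 1, length.out = n),
                          rnorm(n, 50, 5), sigma = runif(n, 1, 3),
                          mask = c(rep(TRUE, 6), FALSE, TRUE))
  prior <- runif(n, 0.5, 2)
  f <- runif(n, 30, 70)
  for (pr in list(NULL, prior)) {
    g <- mer_gradients(f, s, prior = pr)
    eps <- 1e-5
    for (k in seq_len(n)) {
      up <- f; up[k] <- f[k] + eps
      dn <- f; dn[k] <- f[k] - eps
      fd_s <- (shannon_entropy(up, pr) - shannon_entropy(dn, pr)) / (2 * eps)
      fd_c <- (chi_squared(up, s) - chi_squared(dn, s)) / (2 * eps)
      expect_equal(g$grad_entropy[k], fd_s, tolerance = 1e-5)
      expect_equal(g$grad_chi_sq[k], fd_c, tolerance = 1e-5)
    }
  }
})

test_that("gradients vanish where theory says they must", {
  s <- noisy_spectrum(10)
  g <- mer_gradients(s$intensity - min(s$intensity) + 1, s)
  # f = d would give zero chi gradient; check directly on a positive copy
  s2 <- s; s2$intensity <- abs(s$intensity) + 1
  g2 <- mer_gradients(s2$intensity, s2)
  expect_equal(g2$grad_chi_sq, rep(0, 120))
  gu <- mer_gradients(rep(5, 120), s)
  expect_equal(max(abs(gu$grad_entropy)), 0, tolerance = 1e-10)
})

test_that("termination metric is a squared unit-vector distance", {
  g <- rnorm(50)
  expect_equal(termination_metric(g, 2 * g), 0)            # parallel
  expect_equal(termination_metric(g, -g), 2)               # anti-parallel
  u <- c(1, rep(0, 9)); v <- c(0, 1, rep(0, 8))
  expect_equal(termination_metric(u, v), 1)                # orthogonal
  expect_equal(termination_metric(numeric(3), numeric(3)), 0)
  expect_error(termination_metric(numeric(3), c(1, 0, 0)), "zero-norm")
})

test_that("the existence test flags over-noisy data", {
  tiny <- default_truth
  tiny$sigma <- rep(10, 120)                 # 0.1% of the Rayleigh peak
  expect_true(me_solution_exists(tiny))
  # uniform data with unit residual scale: the uniform solution already fits
  set.seed(5)
  flat <- brillouin_spectrum(default_model$frequency_ghz,
                             rnorm(120, 100, 1), sigma = 2)
  expect_false(me_solution_exists(flat))
})

test_that("reconstruction satisfies the consistency contract at low noise", {
  s <- noisy_spectrum(100, seed = 1)         # sigma = 1% of Brillouin peak
  r <- mer_reconstruct(s)
  expect_true(r$exists)
  expect_lte(r$chi_sq, 1)
  expect_lt(max(abs(r$f - default_truth$intensity)), 3 * s$sigma[1])
  expect_true(all(r$f > 0))
})

test_that("the Lagrangian is monotone non-decreasing over iterations", {
  for (seed in 1:3) {
    r <- mer_reconstruct(noisy_spectrum(5, seed))
    expect_true(all(diff(r$q_trace) > -1e-8 * pmax(1, abs(r$q_trace[-1]))))
  }
})

test_that("convergence lands on the constraint surface", {
  # converged runs under the default multiplier: metric < 0.01 implies the
  # gradients are parallel and the misfit sits near the target chi0^2 = 1
  for (snr in c(1, 3, 10)) {
    r <- mer_reconstruct(noisy_spectrum(snr, seed = snr + 40))
    if (r$converged) {
      expect_lt(r$term_metric, 0.01)
      expect_gte(r$chi_sq, 0.5)
      expect_lte(r$chi_sq, 1.5)
    }
  }
})

test_that("reconstruction is scale invariant", {
  s <- noisy_spectrum(5, seed = 8)
  k <- 137.5
  s2 <- s
  s2$intensity <- s$intensity * k
  s2$sigma <- s$sigma * k
  r1 <- mer_reconstruct(s, options = mer_options(max_iters = 150))
  r2 <- mer_reconstruct(s2, options = mer_options(max_iters = 150))
  expect_equal(r2$f / sum(r2$f), r1$f / sum(r1$f), tolerance = 1e-9)
})

test_that("masked pixels never influence the reconstruction", {
  s <- noisy_spectrum(5, seed = 13)
  s <- mask_range(s, -2, 2)
  s2 <- s
  s2$intensity[!s2$mask] <- s2$intensity[!s2$mask] + 5000
  r1 <- mer_reconstruct(s, prior = default_peaks)
  r2 <- mer_reconstruct(s2, prior = default_peaks)
  expect_identical(r1$f, r2$f)
})

test_that("a missing ME solution short-circuits with exists = FALSE", {
  set.seed(5)
  flat <- brillouin_spectrum(default_model$frequency_ghz,
                             rnorm(120, 100, 1), sigma = 2,
                             meta = list(snr = 1))
  r <- mer_reconstruct(flat)
  expect_false(r$exists)
  expect_false(r$converged)
  expect_identical(r$n_iters, 0L)
})

test_that("option validation catches inconsistent settings", {
  expect_error(mer_options(wolfe_c1 = 0.95, wolfe_c2 = 0.9), "wolfe")
  expect_error(mer_options(chi0_sq = 0), "positive")
  expect_error(mer_options(lambda = -1), "positive")
  expect_error(mer_options(term_threshold = 0), "positive")
})

test_that("the prior pulls the reconstruction towards the model shape", {
  s <- noisy_spectrum(1, seed = 77)
  r_prior <- mer_reconstruct(s, prior = default_peaks)
  r_plain <- mer_reconstruct(s)
  m <- mer_prior(default_peaks, default_model)
  d_prior <- sum((r_prior$f / sum(r_prior$f) - m)^2)
  d_plain <- sum((r_plain$f / sum(r_plain$f) - m)^2)
  expect_lt(d_prior, d_plain)
})
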