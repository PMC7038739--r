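test_that("Debye permittivity reproduces closed-form limits", {
  brain <- tissue_library()$brain
  # static limit of the real part: eps_inf + delta_eps
  expect_equal(debye_eps_real(brain, 1), 40, tolerance = 1e-6)
  # dispersion-free model returns eps_inf exactly at any frequency
  flat <- debye_model(7.3, 0, 0, 50e-12)
  expect_identical(debye_permittivity(flat, 2.2e9), 7.3 + 0i)
  # at omega * tau = 1 the pole contributes delta_eps/2 to both parts
  m <- debye_model(4, 12, 0, 20e-12)
  f1 <- 1 / (2 * pi * m$tau)
  eps <- debye_permittivity(m, f1)
  expect_equal(Re(eps), 4 + 6, tolerance = 1e-12)
  expect_equal(Im(eps), -6, tolerance = 1e-12)
  expect_error(debye_permittivity(m, 0), "positive")
  expect_error(debye_model(0.5, 1, 0, 1e-12), "eps_inf")
  expect_error(debye_model(10, -1, 0, 1e-12), "delta_eps")
  expect_error(debye_model(10, 1, 0, 0), "tau")
})

test_that("real permittivity is non-increasing in frequency for valid models", {
  set.seed(11)
  freqs <- seq(0.2e9, 3e9, length.out = 40)
  for (i in 1:100) {
    m <- debye_model(1 + runif(1, 0, 30), runif(1, 0, 50),
                     runif(1, 0, 2), 10^runif(1, -12.5, -9.5))
    er <- debye_eps_real(m, freqs)
    expect_true(all(diff(er) <= 1e-9))
  }
})

test_that("contrast scaling hits the stated ratio at the reference frequency", {
  lib <- tissue_library()
  er_brain <- debye_eps_real(lib$brain, 1e9)
  m25 <- scale_contrast(lib$brain, -0.25)
  expect_equal(debye_eps_real(m25, 1e9), 0.75 * er_brain, tolerance = 1e-12)
  m50 <- scale_contrast(lib$brain, -0.50)
  expect_equal(debye_eps_real(m50, 1e9), 0.50 * er_brain, tolerance = 1e-12)
  expect_identical(scale_contrast(lib$brain, 0), lib$brain)
  expect_error(scale_contrast(lib$brain, -1), "factor")
})

test_that("contrast scalings compose multiplicatively at the reference", {
  set.seed(4)
  for (i in 1:20) {
    m <- debye_model(1 + runif(1, 1, 20), runif(1, 1, 40),
                     runif(1, 0, 1), 10^runif(1, -12, -10))
    a <- runif(1, -0.5, 0.6); b <- runif(1, -0.5, 0.6)
    m1 <- scale_contrast(scale_contrast(m, a), b)
    m2 <- scale_contrast(m, (1 + a) * (1 + b) - 1)
    expect_equal(debye_eps_real(m1, 1e9), debye_eps_real(m2, 1e9),
                 tolerance = 1e-9)
    expect_equal(m1$delta_eps, m2$delta_eps, tolerance = 1e-9)
  }
})

test_that("Debye fitting round-trips the generating model", {
  lib <- tissue_library()
  freqs <- seq(0.5e9, 2.5e9, length.out = 20)
  fit <- fit_debye(freqs, debye_permittivity(lib$brain, freqs))
  expect_equal(fit$eps_inf, lib$brain$eps_inf, tolerance = 0.01)
  expect_equal(fit$delta_eps, lib$brain$delta_eps, tolerance = 0.01)
  expect_equal(fit$sigma_s, lib$brain$sigma_s, tolerance = 0.01)
  expect_equal(fit$tau, lib$brain$tau, tolerance = 0.01)
  # degenerate dispersion: constant permittivity
  flat <- fit_debye(freqs, rep(6 + 0i, 20))
  expect_lt(flat$delta_eps, 1e-3)
  expect_equal(flat$eps_inf, 6, tolerance = 1e-3)
  expect_error(fit_debye(c(1e9, 2e9), c(1 + 0i, 1 + 0i)), "insufficient")
  expect_error(fit_debye(c(1e9, 1.1e9, 1.2e9, 1.3e9),
                         rep(5 + 0i, 4)), "insufficient")
})

test_that("fit/evaluate round-trip stays below 1% across random models", {
  set.seed(21)
  freqs <- seq(0.5e9, 2.5e9, length.out = 25)
  worst <- 0
  for (i in 1:100) {
    m <- debye_model(1 + runif(1, 2, 25), runif(1, 2, 40),
                     runif(1, 0.01, 1.5), 10^runif(1, -11.5, -10))
    fit <- fit_debye(freqs, debye_permittivity(m, freqs))
    rel <- abs(debye_permittivity(fit, freqs) / debye_permittivity(m, freqs) - 1)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 0.01)
})

test_that("tissue library carries the published curve-fit parameters", {
  lib <- tissue_library()
  expect_identical(lib$brain$delta_eps, 30)
  expect_identical(lib$brain$eps_inf, 10)
  expect_identical(lib$brain$sigma_s, 0.147)
  expect_identical(lib$brain$provenance, "paper_table3")
  expect_identical(lib$glycerol90$delta_eps, 6.56)
  expect_identical(lib$glycerol90$eps_inf, 16.86)
  expect_identical(lib$glycerol90$sigma_s, 0.3232)
  # blood above brain over 1-2 GHz; ischaemia presets are scaled copies
  for (f in c(1e9, 1.5e9, 2e9))
    expect_gt(debye_eps_real(lib$blood, f), debye_eps_real(lib$brain, f))
  expect_identical(lib$ischemia_25$provenance, "scaled")
  ov <- tissue_library(overrides = list(blood = debye_model(60, 5, 1, 9e-12)))
  expect_identical(ov$blood$eps_inf, 60)
})
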