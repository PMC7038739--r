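test_that("Born prediction matches a full forward-difference oracle", {
  case <- study_get("born_jacobian", function() {
    sc <- stroke_scenario("none", scale = STUDY_SCALE)
    ph <- sc$guess; arr <- sc$array; f <- 1e9
    dom <- reconstruction_domain(ph)
    cell <- dom[round(length(dom) * 0.4)]
    runs <- lapply(seq_len(arr$n), function(m)
      run_forward(ph, source_spec(arr$positions[m, ]), f,
                  receivers = arr$positions))
    S0 <- t(vapply(runs, function(r) r$rx[, 1], complex(arr$n)))
    ph2 <- ph
    ph2$delta_eps[cell] <- ph2$delta_eps[cell] + 0.3
    S1 <- multistatic_scan(ph2, arr, f)$S[[1]]
    w <- 2 * pi * f
    glyc <- tissue_library()$glycerol90
    er <- glyc$eps_inf + glyc$delta_eps / (1 + (w * glyc$tau)^2)
    c0 <- source_constant(ph$spacing, ph$n, f, er)
    sys <- assemble_jacobian(lapply(runs, function(r) r$fields[[1]]),
                             f, dom, ph, c0 = c0)
    list(sys = sys, dS = S1 - S0, dom = dom, cell = cell)
  })
  K <- length(case$dom)
  x <- numeric(2 * K)
  x[which(case$dom == case$cell)] <- 0.3
  pred_r <- drop(case$sys$A %*% x)
  np <- nrow(case$sys$pairs)
  pred <- complex(real = pred_r[1:np], imaginary = pred_r[np + 1:np])
  truth <- as.vector(t(case$dS))
  off <- case$sys$pairs[, 1] != case$sys$pairs[, 2]
  expect_lt(max(abs(pred[off] - truth[off]) / abs(truth[off])), 0.05)
  # zero contrast predicts exactly zero scattering
  expect_identical(drop(case$sys$A %*% numeric(2 * K)), numeric(2 * np))
  # 8 antennas, all pairs: 64 complex pairs = 128 real rows, 2K columns
  expect_identical(dim(case$sys$A), c(128L, 2L * K))
})

test_that("background updates add, clamp, and invert", {
  sc <- stroke_scenario("none", scale = STUDY_SCALE)
  ph <- sc$guess
  dom <- reconstruction_domain(ph)
  K <- length(dom)
  expect_identical(update_background(ph, numeric(2 * K), dom), ph)
  # conductivity driven negative clamps to zero
  x <- numeric(2 * K); x[K + 1] <- -10
  ph2 <- update_background(ph, x, dom)
  expect_identical(ph2$sigma_s[dom[1]], 0)
  # interior add/subtract round-trips when no clamping is active
  set.seed(6)
  x <- c(runif(K, -0.5, 0.5), runif(K, -0.01, 0.01))
  ph3 <- update_background(update_background(ph, x, dom), -x, dom)
  expect_equal(ph3$delta_eps, ph$delta_eps, tolerance = 1e-12)
  expect_equal(ph3$sigma_s, ph$sigma_s, tolerance = 1e-12)
})

test_that("zero calibrated data with a true initial guess is a fixed point", {
  sc <- stroke_scenario("none", scale = STUDY_SCALE)
  scan <- study_get("scan_guess_notarget_fast", function()
    multistatic_scan(sc$guess, sc$array, 1e9, scenario = "no_target"))
  cal <- calibrate(scan, scan, scan)      # identical sets: y = 0
  fit <- dbim_reconstruct(cal, sc$guess, iterations = 2)
  expect_equal(fit$background$delta_eps, sc$guess$delta_eps, tolerance = 1e-10)
  r <- residuals(fit)
  expect_lt(max(r$residual), 1e-10)
})

test_that("same-grid single-target inversion localizes and converges", {
  case <- study_get("inverse_crime_2mm", function() {
    sc <- stroke_scenario("h", scale = STUDY_SCALE, spacing_true = 0.002)
    st <- run_stroke_study(sc, freqs = 1e9, iterations = 15)
    list(sc = sc, st = st)
  })
  r <- residuals(case$st$result)$residual
  expect_lt(r[length(r)], 0.2 * r[1])
  expect_lt(centroid_error_mm(case$st$report, case$sc), 4)
  # modelling surface: methods on the fitted object
  expect_s3_class(case$st$result, "dbim")
  cf <- coef(case$st$result)
  expect_identical(dim(cf$delta_eps), dim(case$sc$guess$delta_eps))
  expect_length(fitted(case$st$result), 1)
  expect_identical(dim(fitted(case$st$result)[[1]]), c(8L, 8L))
})

test_that("permittivity maps re-evaluate the Debye model per frequency", {
  case <- study_get("inverse_crime_2mm", function() {
    sc <- stroke_scenario("h", scale = STUDY_SCALE, spacing_true = 0.002)
    st <- run_stroke_study(sc, freqs = 1e9, iterations = 15)
    list(sc = sc, st = st)
  })
  res <- case$st$result
  m1 <- permittivity_maps(res, 1e9)
  m2 <- predict(res, 1.5e9)
  # same parameter maps, different frequency: images differ only through
  # the dispersion model
  ph <- res$background
  w1 <- 2 * pi * 1e9
  expect_equal(m1$eps_real,
               ph$eps_inf + ph$delta_eps / (1 + (w1 * ph$tau)^2),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m1$eps_real, m2$eps_real)))
  # homogeneous maps give constant images; brain values hit the static limit
  hom <- homogeneous_phantom(n = 60, spacing = 0.002, eps_r = 10,
                             delta_eps = 30, sigma_s = 0.147, tau = 13e-12)
  fake <- structure(list(background = hom, initial = hom, schedule = 1e9,
                         stages = list()), class = "dbim")
  mm <- permittivity_maps(fake, 1e3)
  expect_equal(max(mm$eps_real) - min(mm$eps_real), 0)
  expect_equal(mm$eps_real[1, 1], 40, tolerance = 1e-6)
})

test_that("schedule frequencies must exist in the calibrated data", {
  sc <- stroke_scenario("none", scale = STUDY_SCALE)
  scan <- study_get("scan_guess_notarget_fast", function()
    multistatic_scan(sc$guess, sc$array, 1e9, scenario = "no_target"))
  cal <- calibrate(scan, scan, scan)
  expect_error(dbim_reconstruct(cal, sc$guess, schedule = 2e9), "schedule")
})
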