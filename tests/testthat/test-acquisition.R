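test_that("array-sizing rule reproduces the published antenna count", {
  lib <- tissue_library()
  expect_identical(antenna_count(0.15, 0.5e9, lib$glycerol90), 15L)
  expect_identical(antenna_count(0.15, 1.0e9, lib$glycerol90), 30L)
  expect_identical(antenna_count(0, 1e9, lib$glycerol90), 0L)
  expect_error(antenna_count(0.15, 0, lib$glycerol90), "freq")
})

test_that("antenna count is monotone in radius and frequency", {
  lib <- tissue_library()
  radii <- seq(0.05, 0.3, length.out = 12)
  freqs <- seq(0.3e9, 3e9, length.out = 12)
  cr <- vapply(radii, antenna_count, 0L, freq = 1e9, medium = lib$glycerol90)
  cf <- vapply(freqs, antenna_count, 0L, radius = 0.15, medium = lib$glycerol90)
  expect_true(all(diff(cr) >= 0))
  expect_true(all(diff(cf) >= 0))
})

test_that("array geometry places antennas in the matching medium", {
  spec <- geometry_spec()
  arr <- array_geometry(spec)
  expect_equal(arr$n, 8)
  expect_equal(arr$positions[1, 2], 0)       # antenna 1 on the +x axis
  expect_gt(arr$positions[2, 2], 0)          # counter-clockwise numbering
  a <- spec$brain_semi_axes[1]; b <- spec$brain_semi_axes[2]
  el <- (arr$positions[, 1] / a)^2 + (arr$positions[, 2] / b)^2
  expect_true(all(el > 1))                   # outside the brain
  expect_true(all(rowSums(arr$positions^2) < (spec$tank_diameter / 2)^2))
  expect_error(array_geometry(spec, scale = 2.1), "tank")
})

test_that("noise injection realizes the requested SNR and is reproducible", {
  set.seed(5)
  S <- replicate(100, matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8),
                 simplify = FALSE)
  noisy <- dbimtwist:::add_measurement_noise(S, snr_db = 30, seed = 123)
  snr_emp <- 10 * log10(mean(vapply(seq_along(S), function(i)
    mean(abs(S[[i]])^2) / mean(abs(noisy[[i]] - S[[i]])^2), 0)))
  expect_equal(snr_emp, 30, tolerance = 1)
  noisy2 <- dbimtwist:::add_measurement_noise(S, snr_db = 30, seed = 123)
  expect_identical(noisy, noisy2)
  noisy3 <- dbimtwist:::add_measurement_noise(S, snr_db = 30, seed = 124)
  expect_false(identical(noisy, noisy3))
})

test_that("a multistatic scan yields a full reciprocal transfer matrix", {
  scan <- study_get("scan_guess_notarget", function() {
    sc <- stroke_scenario("none", scale = STUDY_SCALE)
    multistatic_scan(sc$guess, sc$array, 1e9, scenario = "no_target",
                     options = fdtd_options(decay_tol = 1e-12))
  })
  S <- scan$S[[1]]
  expect_equal(dim(S), c(8, 8))
  off <- abs(S - t(S)) / abs(S)
  expect_lt(max(off), 1e-6)
  expect_identical(scan$scenario, "no_target")
})

test_that("antennas inside the phantom are rejected", {
  sc <- stroke_scenario("none", scale = STUDY_SCALE)
  bad <- sc$array
  bad$positions[3, ] <- c(0, 0)
  expect_error(multistatic_scan(sc$guess, bad, 1e9), "matching medium")
})

test_that("native measurement container round-trips losslessly", {
  freqs <- c(0.7e9, 1.1e9, 1.5e9)
  S <- lapply(1:3, function(k)
    matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8))
  arr <- array_geometry(geometry_spec())
  ms <- structure(list(freqs = freqs, S = S, scenario = "target",
                       noise = list(snr_db = 40, seed = 1),
                       provenance = "simulated", array = arr),
                  class = "measurement_set")
  path <- tempfile(fileext = ".json")
  write_measurements(ms, path)
  back <- read_measurements(path)
  expect_equal(back$freqs, freqs)
  for (k in 1:3) expect_equal(back$S[[k]], S[[k]], tolerance = 1e-12)
  expect_identical(back$scenario, "target")
  expect_equal(back$array$positions, arr$positions, tolerance = 1e-12)
})

test_that("Touchstone 8-port files round-trip and malformed files error", {
  set.seed(9)
  freqs <- c(0.5e9, 1.5e9, 2.5e9)
  S <- lapply(1:3, function(k)
    matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8))
  ms <- structure(list(freqs = freqs, S = S, scenario = "target",
                       noise = NULL, provenance = "simulated", array = NULL),
                  class = "measurement_set")
  path <- tempfile(fileext = ".s8p")
  write_touchstone(ms, path)
  back <- read_measurements(path)
  expect_length(back$S, 3)
  expect_equal(dim(back$S[[1]]), c(8, 8))
  expect_equal(back$freqs, freqs)
  for (k in 1:3) expect_equal(back$S[[k]], S[[k]], tolerance = 1e-9)
  expect_identical(back$provenance, "file")
  # wrong port count declared by the extension
  path4 <- sub("s8p$", "s4p", path)
  file.copy(path, path4)
  expect_error(read_touchstone(path4), "port")
  # corrupt data token
  lines <- readLines(path)
  lines[5] <- paste(lines[5], "bogus")
  writeLines(lines, path)
  expect_error(read_touchstone(path), "parse error")
})

test_that("two-port Touchstone files honour the column-major quirk", {
  S21 <- 0.5 - 0.25i
  S12 <- 0.1 + 0.02i
  txt <- c("! two-port fixture", "# MHz S RI R 50",
           paste("100", "0.9 0.0", Re(S21), Im(S21), Re(S12), Im(S12), "0.8 0.0"))
  path <- tempfile(fileext = ".s2p")
  writeLines(txt, path)
  ms <- read_touchstone(path)
  expect_equal(ms$freqs, 100e6)
  expect_equal(ms$S[[1]][2, 1], S21)
  expect_equal(ms$S[[1]][1, 2], S12)
})
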