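test_that("homogeneous-medium field decay matches the cylindrical-wave solution", {
  ph <- homogeneous_phantom(n = 120, spacing = 0.002, eps_r = 20)
  fs <- study_get("homog_run", function()
    run_forward(ph, source_spec(c(0, 0), f0 = 1e9, span = c(0.6e9, 1.4e9)),
                c(0.8e9, 1e9, 1.3e9)))
  at <- function(k, r) {
    nd <- .snap_node_test(ph, c(r, 0))
    list(v = fs$fields[[k]][nd$i, nd$j], rho = nd$pos[1])
  }
  for (k in seq_along(fs$freqs)) {
    a <- at(k, 0.04); b <- at(k, 0.08)   # r and 2r, both >= 5 cells out
    num <- abs(a$v / b$v)
    an <- abs(line_source_field(fs$freqs[k], 20, a$rho) /
                line_source_field(fs$freqs[k], 20, b$rho))
    expect_equal(num, an, tolerance = 0.03)
  }
})

test_that("zero-amplitude excitation produces identically zero fields", {
  ph <- homogeneous_phantom(n = 60, spacing = 0.002)
  src <- source_spec(c(0, 0), f0 = 1e9, span = c(0.7e9, 1.3e9), amplitude = 0)
  fs <- run_forward(ph, src, 1e9)
  # normalization by a zero spectrum is 0/0; the raw DFT must vanish
  expect_true(all(!is.finite(fs$fields[[1]]) | fs$fields[[1]] == 0))
})

test_that("transfer functions are reciprocal in heterogeneous media", {
  sc <- stroke_scenario("h", scale = STUDY_SCALE)
  opt <- fdtd_options(decay_tol = 1e-12)  # tight ring-down truncation
  pos <- sc$array$positions
  r1 <- run_forward(sc$guess, source_spec(pos[1, ]), 1e9, receivers = pos,
                    options = opt)
  r4 <- run_forward(sc$guess, source_spec(pos[4, ]), 1e9, receivers = pos,
                    options = opt)
  expect_lt(abs(r1$rx[4, 1] - r4$rx[1, 1]) / abs(r1$rx[4, 1]), 1e-6)
})

test_that("scattering is linear in weak contrasts (Born regime)", {
  sc <- study_get("born_linearity", function() {
    base <- stroke_scenario("none", scale = STUDY_SCALE)$guess
    arr <- stroke_scenario("none", scale = STUDY_SCALE)$array
    cell <- reconstruction_domain(base)[300]
    run1 <- run_forward(base, source_spec(arr$positions[1, ]), 1e9,
                        receivers = arr$positions)
    perturbed <- function(fac) {
      ph <- base
      ph$delta_eps[cell] <- ph$delta_eps[cell] * (1 + fac)
      run_forward(ph, source_spec(arr$positions[1, ]), 1e9,
                  receivers = arr$positions)
    }
    list(base = run1, p1 = perturbed(0.01), p2 = perturbed(0.02))
  })
  s1 <- sc$p1$rx[, 1] - sc$base$rx[, 1]
  s2 <- sc$p2$rx[, 1] - sc$base$rx[, 1]
  expect_equal(max(abs(s2 - 2 * s1) / abs(s2)), 0, tolerance = 0.05)
  expect_gt(mean(abs(s2)), mean(abs(s1)))  # grows with contrast
})

test_that("scattered_fields differences receiver values and checks inputs", {
  ph <- homogeneous_phantom(n = 60, spacing = 0.002)
  rx <- rbind(c(0.03, 0), c(0, 0.03))
  fs <- run_forward(ph, source_spec(c(-0.03, 0), f0 = 1e9, span = c(0.7e9, 1.3e9)),
                    1e9, receivers = rx)
  z <- scattered_fields(fs, fs)
  expect_true(all(z[[1]] == 0))
  fs2 <- fs; fs2$freqs <- 1.1e9
  expect_error(scattered_fields(fs, fs2), "frequency")
})

test_that("an unstable time step is reported as a stability error", {
  ph <- homogeneous_phantom(n = 60, spacing = 0.002)
  src <- source_spec(c(0, 0), f0 = 1e9, span = c(0.7e9, 1.3e9))
  expect_error(run_forward(ph, src, 1e9, options = fdtd_options(courant = 1.2)),
               "stability")
})

test_that("requesting frequencies outside the source band fails", {
  ph <- homogeneous_phantom(n = 60, spacing = 0.002)
  src <- source_spec(c(0, 0), f0 = 1e9, span = c(0.9e9, 1.1e9))
  expect_error(run_forward(ph, src, 3e9), "bandwidth")
})

test_that("solution error against the analytic field shrinks with the grid", {
  errs <- vapply(c(0.004, 0.002), function(sp) {
    ph <- homogeneous_phantom(n = round(0.24 / sp), spacing = sp, eps_r = 20)
    fs <- run_forward(ph, source_spec(c(0, 0), f0 = 1e9, span = c(0.7e9, 1.3e9)), 1e9)
    nd <- .snap_node_test(ph, c(0.06, 0))
    ref <- .snap_node_test(ph, c(0.03, 0))
    num <- fs$fields[[1]][nd$i, nd$j] / fs$fields[[1]][ref$i, ref$j]
    an <- line_source_field(1e9, 20, nd$pos[1]) / line_source_field(1e9, 20, ref$pos[1])
    abs(num / an - 1)
  }, 0)
  expect_lt(errs[2], errs[1])
})
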