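# Shared study conditions and cached heavy computations.
#
# Reduced-size study: the laboratory geometry scaled to a 150 mm tank, with
# the full-size protocol's grids (1 mm ground truth, 2 mm inversion),
# 8 antennas and 15 DBIM iterations per frequency.

STUDY_SCALE <- 0.5

.study_cache <- new.env(parent = emptyenv())

study_get <- function(key, fn) {
  if (is.null(.study_cache[[key]])) .study_cache[[key]] <- fn()
  .study_cache[[key]]
}

# mean reconstructed eps' over the true target disc (robust quantitative
# readout; single-cell values sit in over/undershoot ripples)
roi_mean_eps <- function(result, sc, freq) {
  maps <- permittivity_maps(result, freq)
  ph <- result$initial
  co <- phantom_coords(ph)
  X <- matrix(co$x, ph$n, ph$n)
  Y <- matrix(co$y, ph$n, ph$n, byrow = TRUE)
  disc <- (X - sc$spec$target_centre[1])^2 + (Y - sc$spec$target_centre[2])^2 <
    (sc$spec$target_diameter / 2)^2
  mean(maps$eps_real[disc])
}

true_target_eps <- function(sc, freq) {
  mat <- switch(sc$target, h = sc$lib$blood, i25 = sc$lib$ischemia_25,
                i50 = sc$lib$ischemia_50, none = sc$lib$brain)
  debye_eps_real(mat, freq)
}

centroid_error_mm <- function(report, sc) {
  1e3 * sqrt(sum((report$centroid - sc$spec$target_centre)^2))
}

# single-frequency recovery case at 1.0 GHz (noise optional), cached
recovery_case <- function(target, snr_db = NULL, seed = NULL) {
  key <- paste0("recovery_", target, "_", if (is.null(snr_db)) "clean" else snr_db)
  study_get(key, function() {
    sc <- stroke_scenario(target, scale = STUDY_SCALE)
    st <- run_stroke_study(sc, freqs = 1.0e9, iterations = 15,
                           noise_snr_db = snr_db, seed = seed)
    list(sc = sc, st = st)
  })
}

# frequency-hopping case over 0.7/1.1/1.5 GHz, cached
hopping_case <- function(target) {
  study_get(paste0("hopping_", target), function() {
    sc <- stroke_scenario(target, scale = STUDY_SCALE)
    st <- run_stroke_study(sc, freqs = c(0.7e9, 1.1e9, 1.5e9), iterations = 15)
    list(sc = sc, st = st)
  })
}

.snap_node_test <- function(ph, pos) dbimtwist:::.snap_node(ph, pos)

# homogeneous lossless phantom for solver validation
homogeneous_phantom <- function(n = 120, spacing = 0.002, eps_r = 20,
                                delta_eps = 0, sigma_s = 0, tau = 1e-12) {
  R <- n * spacing / 2
  structure(list(spacing = spacing, n = n, origin = c(-R, -R),
                 eps_inf = matrix(eps_r, n, n),
                 delta_eps = matrix(delta_eps, n, n),
                 sigma_s = matrix(sigma_s, n, n),
                 tau = matrix(tau, n, n),
                 label = matrix(0L, n, n)),
            class = "phantom_map")
}
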