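#' Excitation specification for the forward solver
#'
#' Line-source excitation: a modulated Gaussian current pulse
#' `I(t) = amplitude * sin(2 pi f0 (t - t0)) * exp(-(t - t0)^2 / (2 s^2))`,
#' with the envelope width `s` chosen so that the spectral magnitude at the
#' edges of `span` stays above `edge_level` of the peak (default 2%, above
#' the 1% floor required for well-conditioned per-frequency normalization).
#'
#' @param position numeric length 2, source position (m)
#' @param f0 centre frequency, Hz
#' @param span numeric length 2, frequency band the pulse must cover, Hz
#' @param amplitude current amplitude (A)
#' @param edge_level minimum spectral magnitude at the band edges, relative
#' @return object of class `source_spec`
#' @export
source_spec <- function(position, f0 = 1.25e9, span = c(0.5e9, 2.5e9),
                        amplitude = 1, edge_level = 0.02) {
  stopifnot(length(position) == 2, f0 > 0, length(span) == 2, all(span > 0))
  df <- max(abs(span - f0))
  s <- sqrt(log(1 / edge_level) / 2) / (pi * df)
  structure(list(position = position, f0 = f0, span = sort(span),
                 amplitude = amplitude, s = s, t0 = 4.5 * s),
            class = "source_spec")
}

# spectral envelope of the modulated Gaussian (positive-frequency lobe)
.source_envelope <- function(src, freq) {
  exp(-2 * pi^2 * src$s^2 * (freq - src$f0)^2)
}

#' FDTD solver options
#'
#' @param pml_cells CPML thickness in cells
#' @param pad_cells homogeneous padding between the phantom and the CPML
#' @param courant fraction of the 2D Courant limit for the time step
#' @param kappa_max,alpha_max,m_pml,sigma_scale CPML grading parameters
#' @param decay_tol stop when field energy falls below this fraction of peak
#' @param max_time_factor cap on simulated time, as a multiple of the
#'   source duration plus slowest-medium domain traversals
#' @return list of options
#' @export
fdtd_options <- function(pml_cells = 10, pad_cells = 4, courant = 0.99,
                         kappa_max = 4, alpha_max = 0.05, m_pml = 3,
                         sigma_scale = 1, decay_tol = 1e-9,
                         max_time_factor = 12) {
  list(pml_cells = pml_cells, pad_cells = pad_cells, courant = courant,
       kappa_max = kappa_max, alpha_max = alpha_max, m_pml = m_pml,
       sigma_scale = sigma_scale, decay_tol = decay_tol,
       max_time_factor = max_time_factor)
}

# snap a physical position to the nearest cell-centre node; returns 1-based
# interior indices and the snapped coordinates
.snap_node <- function(ph, pos) {
  i <- round((pos[1] - ph$origin[1]) / ph$spacing + 0.5)
  j <- round((pos[2] - ph$origin[2]) / ph$spacing + 0.5)
  i <- max(1L, min(ph$n, as.integer(i)))
  j <- max(1L, min(ph$n, as.integer(j)))
  list(i = i, j = j,
       pos = c(ph$origin[1] + (i - 0.5) * ph$spacing,
               ph$origin[2] + (j - 0.5) * ph$spacing))
}

# replicate-pad a matrix by k cells on every side
.pad_matrix <- function(m, k) {
  n <- nrow(m)
  idx <- c(rep(1L, k), seq_len(n), rep(n, k))
  m[idx, idx]
}

#' Run the 2D TMz FDTD forward solver
#'
#' Time-steps a line-source excitation through the dispersive phantom with
#' CPML absorbing boundaries, and extracts complex frequency-domain fields
#' over the full grid by a running DFT. Fields are normalized by the DFT of
#' the source current, so they are per-unit-current transfer functions under
#' the `e^{+j omega t}` convention.
#'
#' @param ph a `phantom_map`
#' @param source a [source_spec()]
#' @param freqs analysis frequencies, Hz (within the source band)
#' @param receivers optional matrix (n x 2) of receiver positions (m); they
#'   are snapped to the nearest grid node
#' @param options [fdtd_options()]
#' @return object of class `field_set`: per-frequency complex field matrices
#'   over the phantom grid, receiver values, snapped positions, and run
#'   diagnostics
#' @export
run_forward <- function(ph, source, freqs, receivers = NULL,
                        options = fdtd_options()) {
  stopifnot(inherits(ph, "phantom_map"), inherits(source, "source_spec"))
  freqs <- sort(as.numeric(freqs))
  env <- .source_envelope(source, freqs)
  if (any(env < 0.01))
    stop("analysis frequency outside the source bandwidth (spectral amplitude < 1% of peak)")

  pad <- options$pml_cells + options$pad_cells
  ei <- .pad_matrix(ph$eps_inf, pad)
  de <- .pad_matrix(ph$delta_eps, pad)
  sg <- .pad_matrix(ph$sigma_s, pad)
  tu <- .pad_matrix(ph$tau, pad)

  dx <- ph$spacing
  vmax <- .c0 / sqrt(min(ei))
  dt <- options$courant * dx / (vmax * sqrt(2))

  # source timing and time budget
  tt <- function(t) source$amplitude *
    sin(2 * pi * source$f0 * (t - source$t0)) * exp(-(t - source$t0)^2 / (2 * source$s^2))
  t_src_end <- source$t0 + 6.1 * source$s
  vmin <- .c0 / sqrt(max(ei + de))
  t_max <- options$max_time_factor * (t_src_end + nrow(ei) * dx * sqrt(2) / vmin)
  nsteps <- ceiling(t_max / dt)
  wav <- tt((seq_len(nsteps) - 0.5) * dt)
  src_end_step <- ceiling(t_src_end / dt)

  sn <- .snap_node(ph, source$position)
  out <- fdtd_run_cpp(ei, de, sg, tu, dx, dt, as.integer(nsteps),
                      sn$i - 1L + pad, sn$j - 1L + pad, wav, freqs,
                      as.integer(options$pml_cells), options$kappa_max,
                      options$alpha_max, options$m_pml, options$sigma_scale,
                      ei[1, 1], options$decay_tol, 25L,
                      as.integer(src_end_step))
  if (isTRUE(out$diverged))
    stop(sprintf(paste0("numerical-stability error: field divergence after %d steps ",
                        "(dx=%.3g m, dt=%.3g s, courant=%.3g)"),
                 out$steps_run, dx, dt, options$courant))

  W <- out$src_spectrum
  sel <- pad + seq_len(ph$n)
  fields <- lapply(seq_along(freqs), function(k) out$fields[[k]][sel, sel] / W[k])

  rx <- NULL; rx_pos <- NULL
  if (!is.null(receivers)) {
    receivers <- as.matrix(receivers)
    nodes <- lapply(seq_len(nrow(receivers)), function(r) .snap_node(ph, receivers[r, ]))
    rx_pos <- t(vapply(nodes, function(nd) nd$pos, numeric(2)))
    rx <- vapply(seq_along(freqs), function(k)
      vapply(nodes, function(nd) fields[[k]][nd$i, nd$j], complex(1)), complex(length(nodes)))
    rx <- matrix(rx, nrow = nrow(receivers))
  }
  structure(list(freqs = freqs, fields = fields, rx = rx, rx_positions = rx_pos,
                 src_position = sn$pos, src_spectrum = W, spacing = dx,
                 n = ph$n, origin = ph$origin, steps_run = out$steps_run),
            class = "field_set")
}

#' Scattered receiver fields from target and background runs
#'
#' Element-wise difference of the receiver values of two [run_forward()]
#' field sets (or two measurement matrices) sharing a frequency list.
#'
#' @param target_run,background_run `field_set`s with receiver values
#' @return list of complex receiver vectors, one per frequency
#' @export
scattered_fields <- function(target_run, background_run) {
  if (!isTRUE(all.equal(target_run$freqs, background_run$freqs)))
    stop("frequency lists differ between runs")
  if (is.null(target_run$rx) || is.null(background_run$rx))
    stop("both runs must carry receiver values")
  lapply(seq_along(target_run$freqs), function(k)
    target_run$rx[, k] - background_run$rx[, k])
}

#' Analytic 2D line-source field
#'
#' Field of a unit-amplitude time-harmonic line current in a homogeneous
#' medium: `E = -(omega mu0 / 4) H0^(2)(k rho)` under `e^{+j omega t}`.
#' Only lossless (real permittivity) media are supported, which is all the
#' solver validation and source-constant calibration require.
#'
#' @param freq frequency, Hz
#' @param eps_r real relative permittivity
#' @param rho radial distance(s), m
#' @return complex field value(s) per unit line current
#' @export
line_source_field <- function(freq, eps_r, rho) {
  w <- 2 * pi * freq
  k <- w * sqrt(eps_r) / .c0
  h02 <- besselJ(k * rho, 0) - 1i * besselY(k * rho, 0)
  -(w * .mu0 / 4) * h02
}

# package-level cache for the source-constant calibration
.fdtd_cache <- new.env(parent = emptyenv())

#' Discrete source-constant calibration
#'
#' The FDTD fields are per-unit-current transfer functions up to a small
#' discretization-dependent complex constant. This runs the solver once in a
#' homogeneous lossless medium on the same grid and compares against the
#' analytic line-source solution at a ring of radii, returning the mean
#' complex ratio FDTD/analytic. Used to put Born-approximation predictions
#' on the solver's absolute scale. Results are cached per
#' (spacing, grid size, frequency, permittivity).
#'
#' @param spacing grid spacing, m
#' @param n grid size (cells per side)
#' @param freq frequency, Hz
#' @param eps_r real relative permittivity of the reference medium
#' @param options [fdtd_options()]
#' @return complex scalar
#' @export
source_constant <- function(spacing, n, freq, eps_r, options = fdtd_options()) {
  key <- sprintf("%.6g_%d_%.6g_%.6g", spacing, n, freq, eps_r)
  if (!is.null(.fdtd_cache[[key]])) return(.fdtd_cache[[key]])
  R <- n * spacing / 2
  ph <- structure(list(spacing = spacing, n = n, origin = c(-R, -R),
                       eps_inf = matrix(eps_r, n, n),
                       delta_eps = matrix(0, n, n),
                       sigma_s = matrix(0, n, n),
                       tau = matrix(1e-12, n, n),
                       label = matrix(0L, n, n)),
                  class = "phantom_map")
  src <- source_spec(c(0, 0), f0 = freq, span = freq * c(0.6, 1.4))
  fs <- run_forward(ph, src, freq, options = options)
  ctr <- .snap_node(ph, c(0, 0))
  radii <- seq(0.18, 0.32, length.out = 8) * n * spacing
  ratios <- vapply(radii, function(r) {
    nd <- .snap_node(ph, ctr$pos + c(r, 0))
    rho <- sqrt(sum((nd$pos - ctr$pos)^2))
    fs$fields[[1]][nd$i, nd$j] / line_source_field(freq, eps_r, rho)
  }, complex(1))
  val <- mean(ratios)
  .fdtd_cache[[key]] <- val
  val
}
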