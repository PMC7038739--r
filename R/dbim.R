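#' Reconstruction-domain cell indices of a phantom
#'
#' The inverse problem is restricted to the brain ellipse: every cell whose
#' label is not the matching medium.
#'
#' @param ph a `phantom_map`
#' @return integer vector of linear cell indices
#' @export
reconstruction_domain <- function(ph) {
  which(ph$label != .LBL[["tank"]])
}

#' Assemble the linearized (distorted-Born) system matrix
#'
#' Under the distorted Born approximation the scattered field at receiver n
#' with transmitter m is linear in the contrast between the unknown and the
#' current background:
#' `Es(rn, rm) = j w eps0 integral Eb(r, rm) Eb(r, rn) O(r) dr`,
#' with both background fields taken from line-source runs on the current
#' background. The unknowns are per-cell perturbations of the Debye
#' dispersion magnitude and static conductivity, so each cell contributes
#' two columns with complex sensitivities `1/(1 + j w tau)` and
#' `1/(j w eps0)`. Rows are split into real and imaginary parts to give a
#' real system compatible with real-valued soft thresholding. The solver's
#' discrete source constant `c0` (see [source_constant()]) puts the
#' prediction on the same absolute scale as the solver's receiver values.
#'
#' @param fields list over transmitters of full-grid complex background
#'   fields at `freq` (from [run_forward()])
#' @param freq frequency, Hz
#' @param domain integer cell indices (see [reconstruction_domain()])
#' @param background the current background `phantom_map`
#' @param c0 complex source constant
#' @param pairs optional 2-column matrix of (tx, rx) index pairs; default all
#' @param rx_nodes matrix of receiver node indices (tx-independent), as
#'   produced internally from the antenna positions
#' @return list with the real stacked matrix `A` (2 pairs x 2K), the complex
#'   pair matrix `Ac`, and bookkeeping indices
#' @export
assemble_jacobian <- function(fields, freq, domain, background, c0 = 1 + 0i,
                              pairs = NULL, rx_nodes = NULL) {
  M <- length(fields)
  if (is.null(pairs))
    pairs <- cbind(tx = rep(seq_len(M), each = M), rx = rep(seq_len(M), M))
  w <- 2 * pi * freq
  dA <- background$spacing^2
  # background field value at every domain cell for each antenna
  G <- vapply(fields, function(F) F[domain], complex(length(domain)))
  base <- (1i * w * .eps0 / c0) * dA
  Ac <- base * (G[, pairs[, 1], drop = FALSE] * G[, pairs[, 2], drop = FALSE])
  Ac <- t(Ac)  # pairs x K
  tau_d <- background$tau[domain]
  s_de <- 1 / (1 + 1i * w * tau_d)
  s_sg <- 1 / (1i * w * .eps0)
  Acz <- cbind(sweep(Ac, 2, s_de, "*"), Ac * s_sg)
  A <- rbind(Re(Acz), Im(Acz))
  list(A = A, Ac = Acz, pairs = pairs, domain = domain, freq = freq)
}

#' Add a contrast update to the background phantom
#'
#' Adds the per-cell dispersion-magnitude and conductivity perturbations to
#' the background's Debye maps over the reconstruction domain, clamping to
#' physical bounds (`delta_eps` in `[0, de_cap]`, `sigma_s` in
#' `[0, sigma_cap]`). `eps_inf` and `tau` are frozen.
#'
#' @param background a `phantom_map`
#' @param x real update vector of length `2 * length(domain)`:
#'   dispersion-magnitude block then conductivity block
#' @param domain integer cell indices
#' @param de_cap,sigma_cap clamping bounds
#' @export
update_background <- function(background, x, domain,
                              de_cap = 80, sigma_cap = 10) {
  K <- length(domain)
  stopifnot(length(x) == 2 * K)
  background$delta_eps[domain] <-
    pmin(pmax(background$delta_eps[domain] + x[seq_len(K)], 0), de_cap)
  background$sigma_s[domain] <-
    pmin(pmax(background$sigma_s[domain] + x[K + seq_len(K)], 0), sigma_cap)
  background
}

#' Reconstruct permittivity maps with DBIM-TwIST
#'
#' The distorted Born iterative method: at each outer iteration the forward
#' solver is re-run on the current background for every antenna, the
#' data residual is formed against the calibrated scattered-field data, the
#' linearized system is assembled ([assemble_jacobian()]) and solved with
#' TwIST ([twist_solve()]), and the solution is added to the background
#' ([update_background()]). Frequencies in the schedule are processed in
#' ascending order ("frequency hopping"): the final background of one stage
#' seeds the next. The same number of iterations is run at every frequency
#' (15 by default).
#'
#' @param data a [calibrate()]d data object (carries the antenna array)
#' @param initial the initial-guess `phantom_map` (also defines the
#'   reconstruction domain and the simulated baseline)
#' @param schedule frequencies to invert, Hz; default: all data frequencies,
#'   ascending
#' @param iterations DBIM iterations per frequency stage
#' @param solver a [twist_params()]
#' @param options [fdtd_options()] for the inner forward runs
#' @param source_args overrides passed to [source_spec()]
#' @param divergence_factor abort the stage if the residual norm exceeds
#'   this multiple of the stage's initial residual
#' @param verbose print per-iteration residuals
#' @return an object of class `dbim`; see [coef.dbim()], [plot.dbim()],
#'   [permittivity_maps()]
#' @export
dbim_reconstruct <- function(data, initial, schedule = NULL, iterations = 15,
                             solver = twist_params(), options = fdtd_options(),
                             source_args = list(), divergence_factor = 10,
                             verbose = FALSE) {
  stopifnot(inherits(data, "calibrated_data"), inherits(initial, "phantom_map"))
  if (is.null(schedule)) schedule <- data$freqs
  schedule <- sort(as.numeric(schedule))
  if (!all(vapply(schedule, function(f) any(abs(data$freqs - f) < 1e-3), TRUE)))
    stop("schedule contains frequencies absent from the calibrated data")
  array <- data$array
  if (is.null(array)) stop("calibrated data carry no antenna array geometry")
  M <- array$n
  domain <- reconstruction_domain(initial)
  K <- length(domain)

  # simulated baseline on the initial background, all stage frequencies at once
  base_runs <- lapply(seq_len(M), function(m) {
    src <- do.call(source_spec, c(list(position = array$positions[m, ]), source_args))
    run_forward(initial, src, schedule, receivers = array$positions,
                options = options)
  })
  S0 <- lapply(seq_along(schedule), function(k)
    t(vapply(base_runs, function(r) r$rx[, k], complex(M))))

  # matching-medium real permittivity per stage, for the source constant
  corner_eps <- function(ph, f) {
    w <- 2 * pi * f
    ph$eps_inf[1, 1] + ph$delta_eps[1, 1] / (1 + (w * ph$tau[1, 1])^2)
  }

  bg <- initial
  res_log <- NULL
  stages <- vector("list", length(schedule))
  fitted_S <- vector("list", length(schedule))
  for (s in seq_along(schedule)) {
    f <- schedule[s]
    kf <- which.min(abs(data$freqs - f))
    yk <- data$y[[kf]]
    keep <- which(!is.na(t(yk)))  # row-major pair order (tx-major)
    pairs <- cbind(tx = rep(seq_len(M), each = M), rx = rep(seq_len(M), M))[keep, , drop = FALSE]
    y_cal <- t(yk)[keep]
    c0 <- source_constant(initial$spacing, initial$n, f, corner_eps(initial, f),
                          options = options)
    res0 <- NA_real_
    for (it in seq_len(iterations)) {
      runs <- lapply(seq_len(M), function(m) {
        src <- do.call(source_spec, c(list(position = array$positions[m, ]), source_args))
        run_forward(bg, src, f, receivers = array$positions, options = options)
      })
      Sk <- t(vapply(runs, function(r) r$rx[, 1], complex(M)))
      model_scatter <- t(Sk - S0[[s]])[keep]
      y_res <- y_cal - model_scatter
      rnorm_ <- sqrt(sum(abs(y_res)^2))
      if (it == 1) res0 <- rnorm_
      if (rnorm_ > divergence_factor * res0)
        stop(sprintf("divergence error: residual %.3g exceeds %g x initial at stage %.3g GHz, iteration %d",
                     rnorm_, divergence_factor, f / 1e9, it))
      if (verbose)
        cat(sprintf("stage %.3g GHz iter %2d residual %.4g\n", f / 1e9, it, rnorm_))
      res_log <- rbind(res_log,
                       data.frame(stage = s, freq = f, iteration = it,
                                  residual = rnorm_))
      fields <- lapply(runs, function(r) r$fields[[1]])
      sys <- assemble_jacobian(fields, f, domain, bg, c0 = c0, pairs = pairs)
      yv <- c(Re(y_res), Im(y_res))
      sol <- twist_solve(sys$A, yv, solver)
      bg <- update_background(bg, sol$x, domain)
      if (it == iterations) fitted_S[[s]] <- Sk
    }
    stages[[s]] <- list(freq = f, delta_eps = bg$delta_eps,
                        sigma_s = bg$sigma_s)
  }
  structure(list(background = bg, initial = initial, domain = domain,
                 schedule = schedule, iterations = iterations,
                 residuals = res_log, stages = stages, array = array,
                 fitted_S = fitted_S, solver = solver,
                 call = match.call()),
            class = "dbim")
}

#' Complex-permittivity images from a reconstruction
#'
#' Evaluates the reconstructed Debye maps at the requested frequency. The
#' imaginary part is reported as the total loss magnitude including the
#' conductivity term.
#'
#' @param result a `dbim` object
#' @param freq frequency, Hz
#' @param stage evaluate the maps after this stage (default: final)
#' @return list with matrices `eps_real`, `eps_imag` and the `freq`
#' @export
permittivity_maps <- function(result, freq, stage = NULL) {
  stopifnot(inherits(result, "dbim"))
  ph <- result$background
  if (!is.null(stage)) {
    st <- result$stages[[stage]]
    ph$delta_eps <- st$delta_eps
    ph$sigma_s <- st$sigma_s
  }
  eps <- phantom_permittivity(ph, freq)
  list(eps_real = Re(eps), eps_imag = -Im(eps), freq = freq)
}

#' @export
print.dbim <- function(x, ...) {
  cat("DBIM-TwIST reconstruction\n")
  cat(sprintf("  schedule: %s GHz, %d iterations/stage\n",
              paste(sprintf("%.2f", x$schedule / 1e9), collapse = " -> "),
              x$iterations))
  r <- x$residuals
  for (s in unique(r$stage)) {
    rs <- r$residual[r$stage == s]
    cat(sprintf("  stage %d (%.2f GHz): residual %.3g -> %.3g\n",
                s, x$schedule[s] / 1e9, rs[1], rs[length(rs)]))
  }
  invisible(x)
}

#' @export
summary.dbim <- function(object, freq = NULL, ...) {
  if (is.null(freq)) freq <- max(object$schedule)
  maps <- permittivity_maps(object, freq)
  dom <- object$domain
  out <- list(freq = freq,
              eps_real_range = range(maps$eps_real[dom]),
              eps_imag_range = range(maps$eps_imag[dom]),
              residuals = object$residuals,
              schedule = object$schedule)
  class(out) <- "summary.dbim"
  out
}

#' @export
print.summary.dbim <- function(x, ...) {
  cat(sprintf("DBIM-TwIST reconstruction summary at %.2f GHz\n", x$freq / 1e9))
  cat(sprintf("  eps' over domain: [%.2f, %.2f]\n", x$eps_real_range[1], x$eps_real_range[2]))
  cat(sprintf("  eps'' over domain: [%.2f, %.2f]\n", x$eps_imag_range[1], x$eps_imag_range[2]))
  r <- x$residuals
  cat(sprintf("  total residual decrease: %.3g -> %.3g over %d iterations\n",
              r$residual[1], r$residual[nrow(r)], nrow(r)))
  invisible(x)
}

#' Reconstructed Debye-parameter maps
#' @param object a `dbim` object
#' @param ... unused
#' @return list with matrices `delta_eps` and `sigma_s`
#' @export
coef.dbim <- function(object, ...) {
  list(delta_eps = object$background$delta_eps,
       sigma_s = object$background$sigma_s)
}

#' Per-iteration residual norms
#' @param object a `dbim` object
#' @param ... unused
#' @export
residuals.dbim <- function(object, ...) object$residuals

#' Final modelled transfer matrices per stage
#' @param object a `dbim` object
#' @param ... unused
#' @export
fitted.dbim <- function(object, ...) object$fitted_S

#' Predict permittivity maps at a frequency
#' @param object a `dbim` object
#' @param freq frequency, Hz
#' @param ... unused
#' @export
predict.dbim <- function(object, freq = max(object$schedule), ...) {
  permittivity_maps(object, freq)
}

#' @export
plot.dbim <- function(x, freq = max(x$schedule), part = c("real", "imag"), ...) {
  part <- match.arg(part)
  maps <- permittivity_maps(x, freq)
  img <- if (part == "real") maps$eps_real else maps$eps_imag
  co <- phantom_coords(x$background)
  graphics::image(co$x * 1e3, co$y * 1e3, img, asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("reconstructed %s(eps) at %.2f GHz", part, freq / 1e9), ...)
  graphics::points(x$array$positions * 1e3, pch = 4)
  invisible(x)
}
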