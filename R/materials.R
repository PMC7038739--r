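#' @useDynLib dbimtwist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median coef
NULL

# physical constants (SI); shared across modules
.c0   <- 299792458
.eps0 <- 8.8541878128e-12
.mu0  <- 1.25663706212e-6

#' Single-pole Debye dispersion model
#'
#' Constructs a dispersive material model
#' \deqn{\epsilon(\omega) = \epsilon_\infty + \frac{\Delta\epsilon}{1 + j\omega\tau}
#'       + \frac{\sigma_s}{j\omega\epsilon_0}}
#' under the \eqn{e^{+j\omega t}} time convention, so that physical loss
#' corresponds to a negative imaginary part.
#'
#' @param eps_inf relative permittivity at infinite frequency (>= 1)
#' @param delta_eps dispersion magnitude (>= 0)
#' @param sigma_s static conductivity in S/m (>= 0)
#' @param tau relaxation time in seconds (> 0)
#' @param name optional material name
#' @param provenance one of `"paper_table3"`, `"scaled"`, `"implementer_default"`
#' @return an object of class `debye_model`
#' @export
#' @examples
#' brain <- debye_model(10, 30, 0.147, 13e-12, name = "brain")
#' debye_permittivity(brain, 1e9)
debye_model <- function(eps_inf, delta_eps, sigma_s, tau,
                        name = NULL, provenance = "implementer_default") {
  stopifnot(is.numeric(eps_inf), is.numeric(delta_eps),
            is.numeric(sigma_s), is.numeric(tau))
  if (eps_inf < 1) stop("eps_inf must be >= 1")
  if (delta_eps < 0) stop("delta_eps must be >= 0")
  if (sigma_s < 0) stop("sigma_s must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(eps_inf = eps_inf, delta_eps = delta_eps,
                 sigma_s = sigma_s, tau = tau,
                 name = name, provenance = provenance),
            class = "debye_model")
}

#' @export
print.debye_model <- function(x, ...) {
  cat(sprintf("Debye model%s: eps_inf = %.4g, delta_eps = %.4g, sigma_s = %.4g S/m, tau = %.4g ps [%s]\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              x$eps_inf, x$delta_eps, x$sigma_s, x$tau * 1e12, x$provenance))
  invisible(x)
}

#' Complex relative permittivity of a Debye medium
#'
#' @param model a [debye_model()]
#' @param freq frequency in Hz (vectorised, all > 0)
#' @return complex relative permittivity
#' @export
debye_permittivity <- function(model, freq) {
  if (any(freq <= 0)) stop("frequency must be positive")
  w <- 2 * pi * freq
  model$eps_inf + model$delta_eps / (1 + 1i * w * model$tau) +
    model$sigma_s / (1i * w * .eps0)
}

#' Real (dielectric-constant) part of a Debye medium
#' @inheritParams debye_permittivity
#' @export
debye_eps_real <- function(model, freq) Re(debye_permittivity(model, freq))

#' Contrast-scale a Debye model at a reference frequency
#'
#' Returns a model whose real permittivity at `ref_freq` is `(1 + factor)`
#' times the input's. `delta_eps`, `(eps_inf - 1)` and `sigma_s` are scaled
#' by a common multiplier, which keeps the scaled model a valid Debye medium
#' and makes successive scalings compose exactly at the reference frequency.
#' This implements the ischaemia presets: a -25% or -50% dielectric-constant
#' contrast relative to the average brain phantom at 1 GHz.
#'
#' @param model a [debye_model()]
#' @param factor relative change of the real permittivity (> -1)
#' @param ref_freq reference frequency, Hz (default 1 GHz)
#' @export
scale_contrast <- function(model, factor, ref_freq = 1e9) {
  if (factor <= -1) stop("contrast factor must be > -1")
  if (factor == 0) return(model)
  er <- debye_eps_real(model, ref_freq)
  g <- ((1 + factor) * er - 1) / (er - 1)
  if (g < 0) stop("contrast factor drives eps_inf below 1")
  debye_model(1 + g * (model$eps_inf - 1), g * model$delta_eps,
              g * model$sigma_s, model$tau,
              name = model$name, provenance = "scaled")
}

#' Fit a single-pole Debye model to sampled complex permittivity
#'
#' Bound-constrained least squares on the stacked real and imaginary parts,
#' via Levenberg-Marquardt.
#'
#' @param freq frequencies, Hz (>= 4 distinct values spanning a 2:1 band)
#' @param eps complex relative permittivity samples
#' @return a [debye_model()] with provenance `"implementer_default"`
#' @export
fit_debye <- function(freq, eps) {
  freq <- as.numeric(freq)
  if (length(freq) != length(eps)) stop("freq and eps lengths differ")
  fu <- unique(freq)
  if (length(fu) < 4) stop("insufficient data: need >= 4 distinct frequencies")
  if (max(fu) / min(fu) < 2) stop("insufficient data: frequencies must span at least a 2:1 band")
  resid_fn <- function(p) {
    m <- list(eps_inf = p[1], delta_eps = p[2], sigma_s = p[3], tau = p[4])
    w <- 2 * pi * freq
    em <- m$eps_inf + m$delta_eps / (1 + 1i * w * m$tau) + m$sigma_s / (1i * w * .eps0)
    c(Re(em - eps), Im(em - eps))
  }
  start <- c(max(1, Re(eps[which.max(freq)])),
             max(0.1, Re(eps[which.min(freq)]) - Re(eps[which.max(freq)])),
             max(1e-4, -Im(eps[which.min(freq)]) * 2 * pi * min(freq) * .eps0),
             1 / (2 * pi * stats::median(freq)))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = c(1, 0, 0, 1e-15), upper = c(1e4, 1e4, 1e3, 1e-6),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  debye_model(p[1], p[2], p[3], p[4])
}

#' Named tissue-model library
#'
#' The 90% glycerol-water matching medium and average-brain models carry the
#' published curve-fit parameters (relaxation times are implementation
#' defaults chosen for smooth behaviour over 0.5-2.5 GHz; they are not part
#' of the published fit). Blood/CSF are implementer defaults with the
#' dielectric constant of blood above brain at 1-2 GHz; the ischaemia
#' entries are contrast-scaled copies of brain (-25% and -50% at 1 GHz).
#'
#' @param overrides optional named list of [debye_model()]s replacing entries
#' @return named list of `debye_model`s, class `tissue_library`
#' @export
tissue_library <- function(overrides = NULL) {
  brain <- debye_model(10, 30, 0.147, 13e-12, name = "brain",
                       provenance = "paper_table3")
  glyc  <- debye_model(16.86, 6.56, 0.3232, 400e-12, name = "glycerol90",
                       provenance = "paper_table3")
  blood <- scale_contrast(brain, 0.40)
  blood$name <- "blood"; blood$provenance <- "implementer_default"
  csf <- blood; csf$name <- "csf"
  i25 <- scale_contrast(brain, -0.25); i25$name <- "ischemia_25"
  i50 <- scale_contrast(brain, -0.50); i50$name <- "ischemia_50"
  lib <- list(brain = brain, glycerol90 = glyc, csf = csf, blood = blood,
              ischemia_25 = i25, ischemia_50 = i50)
  if (!is.null(overrides)) {
    stopifnot(all(vapply(overrides, inherits, TRUE, "debye_model")))
    lib[names(overrides)] <- overrides
  }
  structure(lib, class = c("tissue_library", "list"))
}

#' @export
print.tissue_library <- function(x, ...) {
  cat("Tissue library (single-pole Debye):\n")
  for (nm in names(x)) {
    m <- x[[nm]]
    cat(sprintf("  %-12s eps_inf=%6.2f delta_eps=%6.2f sigma_s=%7.4f tau=%6.1f ps  [%s]\n",
                nm, m$eps_inf, m$delta_eps, m$sigma_s, m$tau * 1e12, m$provenance))
  }
  invisible(x)
}
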