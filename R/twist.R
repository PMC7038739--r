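#' TwIST solver parameters
#'
#' Two-step iterative shrinkage/thresholding constants. The two-step
#' coefficients default to the standard construction from an assumed
#' spectral-bound pair `(xi1, xim)` for the normalized system:
#' `rho = (1 - sqrt(xi1/xim)) / (1 + sqrt(xi1/xim))`, `alpha = rho^2 + 1`,
#' `beta = 2 alpha / (xi1 + xim)`. The regularization weight `lambda` is
#' relative: the absolute threshold is `lambda * max|A^T y|` after the
#' system has been column-normalized and scaled to unit spectral norm, so
#' `lambda >= 1` yields the zero solution.
#'
#' @param lambda relative l1 weight (default 1e-3)
#' @param xi1,xim assumed smallest/largest eigenvalue of the normalized
#'   `A^T A` (defaults 1e-4 and 1)
#' @param alpha,beta explicit two-step coefficients (override `xi1`/`xim`);
#'   `alpha` must lie in (0, 2), `beta` must be positive
#' @param max_iter maximum inner iterations (>= 1)
#' @param tol relative-change stopping tolerance
#' @param monotone fall back to a plain IST step whenever the two-step
#'   iterate would increase the objective
#' @param normalize column-normalize the system before solving (makes
#'   `lambda` insensitive to heterogeneous column scales, the sensible
#'   default for the imaging system matrix). Note that with normalization
#'   the `lambda -> 0` limit is the minimum-`||D x||` rather than the
#'   minimum-`||x||` least-squares solution; set `FALSE` to recover the
#'   pseudo-inverse limit on underdetermined systems.
#' @export
twist_params <- function(lambda = 1e-3, xi1 = 1e-4, xim = 1,
                         alpha = NULL, beta = NULL,
                         max_iter = 500, tol = 1e-6, monotone = TRUE,
                         normalize = TRUE) {
  stopifnot(lambda >= 0, xi1 > 0, xim >= xi1, max_iter >= 1, tol >= 0)
  if (is.null(alpha)) {
    rho <- (1 - sqrt(xi1 / xim)) / (1 + sqrt(xi1 / xim))
    alpha <- rho^2 + 1
  }
  if (is.null(beta)) beta <- 2 * alpha / (xi1 + xim)
  if (alpha <= 0 || alpha >= 2) stop("alpha must lie in (0, 2)")
  if (beta <= 0) stop("beta must be positive")
  structure(list(lambda = lambda, alpha = alpha, beta = beta,
                 xi1 = xi1, xim = xim, max_iter = as.integer(max_iter),
                 tol = tol, monotone = isTRUE(monotone),
                 normalize = isTRUE(normalize)),
            class = "twist_params")
}

#' Soft-thresholding (l1 proximal) operator
#'
#' `sign(v) * max(|v| - t, 0)`; for complex values the magnitude is
#' thresholded and the phase preserved.
#'
#' @param v numeric or complex vector
#' @param t threshold (>= 0)
#' @export
soft_threshold <- function(v, t) {
  if (any(t < 0)) stop("threshold must be >= 0")
  a <- abs(v)
  shrink <- pmax(a - t, 0)
  ifelse(a > 0, v * (shrink / a), v * 0)
}

#' Solve an l1-regularized linear system with TwIST
#'
#' Minimizes `0.5 ||y - A x||^2 + lambda ||x||_1` by the two-step iterative
#' shrinkage/thresholding scheme
#' `x_{t+1} = (1 - alpha) x_{t-1} + (alpha - beta) x_t + beta Psi(x_t + A^T (y - A x_t))`,
#' starting from the zero vector with a plain IST first step. Internally the
#' columns of `A` are normalized and the system scaled to unit spectral norm
#' (power-iteration estimate); the solution is rescaled on return, so
#' `params$lambda` is scale-free.
#'
#' @param A real matrix (rows: data, columns: unknowns)
#' @param y real data vector
#' @param params a [twist_params()]
#' @return list with `x` (solution), `objective` (per-iteration trace of the
#'   scaled problem), `iterations`
#' @export
twist_solve <- function(A, y, params = twist_params()) {
  stopifnot(is.matrix(A), nrow(A) == length(y))
  if (isTRUE(params$normalize)) {
    cn <- sqrt(colSums(A^2))
    cn[cn == 0] <- 1
  } else cn <- rep(1, ncol(A))
  An <- sweep(A, 2, cn, "/")
  # spectral norm of the column-normalized system by power iteration
  v <- rep(1 / sqrt(ncol(An)), ncol(An))
  for (i in 1:30) {
    w <- drop(crossprod(An, An %*% v))
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    v <- w / nw
  }
  smax <- sqrt(max(nw, .Machine$double.eps))
  An <- An / smax

  Aty <- drop(crossprod(An, y))
  lam <- params$lambda * max(abs(Aty))
  obj <- function(x, r) 0.5 * sum(r^2) + lam * sum(abs(x))
  grad_step <- function(x, r) soft_threshold(x + drop(crossprod(An, r)), lam)

  x_old <- numeric(ncol(An))
  r_old <- y
  x <- grad_step(x_old, r_old)        # plain IST first step
  r <- y - drop(An %*% x)
  trace <- c(obj(x_old, r_old), obj(x, r))
  it <- 1L
  while (it < params$max_iter) {
    it <- it + 1L
    xg <- grad_step(x, r)
    xn <- (1 - params$alpha) * x_old + (params$alpha - params$beta) * x +
      params$beta * xg
    rn <- y - drop(An %*% xn)
    if (params$monotone && obj(xn, rn) > obj(x, r)) {
      xn <- xg
      rn <- y - drop(An %*% xn)
    }
    if (any(!is.finite(xn)))
      stop("divergence error in TwIST at iteration ", it)
    trace <- c(trace, obj(xn, rn))
    dx <- sqrt(sum((xn - x)^2))
    x_old <- x
    x <- xn
    r <- rn
    if (dx <= params$tol * max(sqrt(sum(x^2)), .Machine$double.eps)) break
  }
  list(x = x / (cn * smax), objective = trace, iterations = it)
}
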