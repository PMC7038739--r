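#' Write a phantom map to a JSON container
#'
#' Portable array container: grid metadata plus the four Debye-parameter
#' fields and the region-label array.
#'
#' @param ph a `phantom_map`
#' @param path output path
#' @export
write_phantom <- function(ph, path) {
  stopifnot(inherits(ph, "phantom_map"))
  obj <- list(format = "dbimtwist-phantom", version = 1L,
              spacing = ph$spacing, n = ph$n, origin = ph$origin,
              eps_inf = ph$eps_inf, delta_eps = ph$delta_eps,
              sigma_s = ph$sigma_s, tau = ph$tau, label = ph$label)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a phantom map from its JSON container
#' @param path input path
#' @export
read_phantom <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "dbimtwist-phantom")
    stop("parse error: not a dbimtwist phantom file: ", path)
  n <- obj$n
  shape <- function(x, mode = "double") matrix(as.vector(x, mode), n, n)
  structure(list(spacing = obj$spacing, n = n, origin = as.numeric(obj$origin),
                 eps_inf = shape(obj$eps_inf), delta_eps = shape(obj$delta_eps),
                 sigma_s = shape(obj$sigma_s), tau = shape(obj$tau),
                 label = shape(obj$label, "integer")),
            class = "phantom_map")
}

#' Write calibrated scattered-field data to JSON
#' @param cal a [calibrate()]d data object
#' @param path output path
#' @export
write_calibrated <- function(cal, path) {
  stopifnot(inherits(cal, "calibrated_data"))
  obj <- list(format = "dbimtwist-calibrated", version = 1L,
              freqs = cal$freqs, method = cal$method,
              floor_rel = cal$floor_rel,
              n_antennas = nrow(cal$y[[1]]),
              positions = cal$array$positions,
              y_re = lapply(cal$y, Re), y_im = lapply(cal$y, Im))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read calibrated scattered-field data from JSON
#' @param path input path
#' @export
read_calibrated <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "dbimtwist-calibrated")
    stop("parse error: not a dbimtwist calibrated-data file: ", path)
  np <- obj$n_antennas
  pick <- function(x, k) {
    m <- if (is.array(x) && length(dim(x)) == 3) x[k, , ] else as.matrix(x[[k]])
    matrix(as.numeric(m), np, np)
  }
  y <- lapply(seq_along(obj$freqs), function(k)
    matrix(complex(real = pick(obj$y_re, k), imaginary = pick(obj$y_im, k)),
           np, np))
  arr <- structure(list(positions = as.matrix(obj$positions), n = np),
                   class = "array_geometry")
  structure(list(freqs = as.numeric(obj$freqs), y = y, method = obj$method,
                 floor_rel = obj$floor_rel, array = arr,
                 reference = NULL),
            class = "calibrated_data")
}
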