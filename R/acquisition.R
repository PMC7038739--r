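#' Antenna array geometry
#'
#' Antennas placed on an ellipse concentric with the brain phantom. Antenna 1
#' sits on the +x axis and the numbering proceeds counter-clockwise, equally
#' spaced in parametric angle. The array ellipse is the phantom ellipse
#' scaled by `scale` (default 1.25), keeping the antennas in the matching
#' medium between phantom and tank wall.
#'
#' @param spec a [geometry_spec()]
#' @param n_antennas number of antennas (default 8)
#' @param scale array-ellipse scale factor relative to the brain ellipse
#' @return object of class `array_geometry` with a positions matrix (m)
#' @export
array_geometry <- function(spec, n_antennas = 8, scale = 1.25) {
  stopifnot(inherits(spec, "geometry_spec"), n_antennas >= 2, scale > 1)
  a <- spec$brain_semi_axes[1] * scale
  b <- spec$brain_semi_axes[2] * scale
  if (max(a, b) >= spec$tank_diameter / 2)
    stop("geometry error: antenna ellipse extends outside the tank")
  th <- 2 * pi * (seq_len(n_antennas) - 1) / n_antennas
  pos <- cbind(a * cos(th), b * sin(th))
  structure(list(positions = pos, n = n_antennas, semi_axes = c(a, b),
                 tank_radius = spec$tank_diameter / 2),
            class = "array_geometry")
}

#' Array-sizing rule M = 2 beta alpha
#'
#' Number of antennas supported by a reconstruction domain of radius `radius`
#' at frequency `freq`: `M = 2 beta alpha` with the wavenumber `beta`
#' computed from the medium's lossless static permittivity
#' (`eps_inf + delta_eps`), rounded to the nearest integer. With the tank
#' radius 0.15 m and the 90% glycerol-water medium at the first working
#' frequency 0.5 GHz this gives 15.
#'
#' @param radius reconstruction-domain radius, m
#' @param freq frequency, Hz
#' @param medium a [debye_model()]
#' @return integer antenna count
#' @export
antenna_count <- function(radius, freq, medium) {
  if (radius < 0 || freq <= 0) stop("radius must be >= 0 and freq > 0")
  beta <- 2 * pi * freq * sqrt(medium$eps_inf + medium$delta_eps) / .c0
  as.integer(round(2 * beta * radius))
}

#' Simulate a full multistatic scan
#'
#' One forward run per transmitting antenna; receiver values at all antennas
#' are assembled into per-frequency complex transfer matrices
#' (`S[[k]][m, n]` = response at antenna n with antenna m transmitting).
#' Optional additive complex Gaussian noise at a stated SNR.
#'
#' @param ph a `phantom_map` (the scenario ground truth)
#' @param array an [array_geometry()]
#' @param freqs frequencies, Hz
#' @param scenario tag, `"target"` or `"no_target"`
#' @param noise_snr_db per-frequency signal-to-noise ratio in dB, or `NULL`
#' @param seed RNG seed for the noise draw
#' @param source_args list of overrides passed to [source_spec()]
#' @param options [fdtd_options()]
#' @param keep_fields keep per-transmitter full-grid fields (used internally
#'   by the reconstruction; large)
#' @return object of class `measurement_set`
#' @export
multistatic_scan <- function(ph, array, freqs, scenario = "target",
                             noise_snr_db = NULL, seed = NULL,
                             source_args = list(), options = fdtd_options(),
                             keep_fields = FALSE) {
  stopifnot(inherits(ph, "phantom_map"), inherits(array, "array_geometry"))
  freqs <- sort(as.numeric(freqs))
  M <- array$n
  # antennas must sit in the matching medium
  for (m in seq_len(M)) {
    nd <- .snap_node(ph, array$positions[m, ])
    if (ph$label[nd$i, nd$j] != .LBL[["tank"]])
      stop("geometry error: antenna ", m, " is not in the matching medium")
  }
  runs <- vector("list", M)
  for (m in seq_len(M)) {
    src <- do.call(source_spec, c(list(position = array$positions[m, ]), source_args))
    runs[[m]] <- run_forward(ph, src, freqs, receivers = array$positions,
                             options = options)
  }
  S <- lapply(seq_along(freqs), function(k)
    t(vapply(runs, function(r) r$rx[, k], complex(M))))
  noise <- NULL
  if (!is.null(noise_snr_db)) {
    S <- add_measurement_noise(S, noise_snr_db, seed)
    noise <- list(snr_db = noise_snr_db, seed = seed)
  }
  structure(list(freqs = freqs, S = S, scenario = scenario, noise = noise,
                 provenance = "simulated", array = array,
                 fields = if (keep_fields) runs else NULL),
            class = "measurement_set")
}

# additive complex Gaussian noise at a fixed per-frequency SNR
add_measurement_noise <- function(S, snr_db, seed = NULL) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  lapply(S, function(Sk) {
    p_sig <- mean(abs(Sk)^2)
    sd_c <- sqrt(p_sig * 10^(-snr_db / 10) / 2)
    Sk + matrix(complex(real = stats::rnorm(length(Sk), 0, sd_c),
                        imaginary = stats::rnorm(length(Sk), 0, sd_c)),
                nrow(Sk), ncol(Sk))
  })
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("Multistatic measurement set [%s, %s]: %d x %d antennas, %d frequencies (%.2f-%.2f GHz)%s\n",
              x$scenario, x$provenance, nrow(x$S[[1]]), ncol(x$S[[1]]),
              length(x$freqs), min(x$freqs) / 1e9, max(x$freqs) / 1e9,
              if (!is.null(x$noise)) sprintf(", noise %g dB SNR", x$noise$snr_db) else ""))
  invisible(x)
}

#' Write a measurement set to its native JSON container
#' @param ms a `measurement_set`
#' @param path output path
#' @export
write_measurements <- function(ms, path) {
  stopifnot(inherits(ms, "measurement_set"))
  obj <- list(format = "dbimtwist-measurements", version = 1L,
              freqs = ms$freqs, scenario = ms$scenario,
              provenance = ms$provenance,
              n_antennas = nrow(ms$S[[1]]),
              positions = ms$array$positions,
              noise = ms$noise,
              S_re = lapply(ms$S, Re), S_im = lapply(ms$S, Im))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a measurement set (native JSON or Touchstone .sNp)
#' @param path input path; `.sNp` files are imported with ports mapped in
#'   index order and tagged `provenance = "file"`
#' @param scenario scenario tag to attach to Touchstone imports
#' @export
read_measurements <- function(path, scenario = "target") {
  if (grepl("\\.s[0-9]+p$", tolower(path)))
    return(read_touchstone(path, scenario = scenario))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "dbimtwist-measurements")
    stop("parse error: not a dbimtwist measurement file: ", path)
  np <- obj$n_antennas
  pick <- function(x, k) {
    # simplification may yield a k x np x np array or a list of matrices
    m <- if (is.array(x) && length(dim(x)) == 3) x[k, , ] else as.matrix(x[[k]])
    matrix(as.numeric(m), np, np)
  }
  S <- lapply(seq_along(obj$freqs), function(k)
    matrix(complex(real = pick(obj$S_re, k), imaginary = pick(obj$S_im, k)),
           np, np))
  arr <- NULL
  if (!is.null(obj$positions))
    arr <- structure(list(positions = as.matrix(obj$positions),
                          n = obj$n_antennas), class = "array_geometry")
  structure(list(freqs = as.numeric(obj$freqs), S = S, scenario = obj$scenario,
                 noise = obj$noise, provenance = obj$provenance, array = arr),
            class = "measurement_set")
}

#' Read a Touchstone v1 .sNp file
#'
#' Supports RI/MA/DB formats and Hz/kHz/MHz/GHz units. For n > 2 ports the
#' network data are taken in row-major matrix order; the classic 2-port
#' column-major quirk (S11 S21 S12 S22) is honoured.
#'
#' @param path file path ending in `.sNp`
#' @param scenario scenario tag for the resulting `measurement_set`
#' @export
read_touchstone <- function(path, scenario = "target") {
  m <- regmatches(path, regexec("\\.s([0-9]+)p$", tolower(path)))[[1]]
  if (length(m) < 2) stop("parse error: cannot infer port count from extension: ", path)
  np <- as.integer(m[2])
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  opt_i <- grep("^\\s*#", lines)
  if (length(opt_i) == 0) stop("parse error: missing '#' option line in ", path)
  opt <- toupper(strsplit(trimws(sub("^\\s*#", "", lines[opt_i[1]])), "\\s+")[[1]])
  unit <- if (length(opt) >= 1) opt[1] else "GHZ"
  fmt <- if (any(opt %in% c("RI", "MA", "DB"))) opt[opt %in% c("RI", "MA", "DB")][1] else "MA"
  fscale <- switch(unit, HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9,
                   stop("parse error: unknown frequency unit '", unit, "' in ", path))
  dat <- lines[-seq_len(opt_i[1])]
  toks <- suppressWarnings(as.numeric(unlist(strsplit(trimws(dat[nzchar(trimws(dat))]), "\\s+"))))
  if (anyNA(toks)) {
    bad <- which(vapply(strsplit(trimws(dat), "\\s+"),
                        function(x) anyNA(suppressWarnings(as.numeric(x[nzchar(x)]))), TRUE))[1]
    stop("parse error: non-numeric network data near data line ", bad, " of ", path)
  }
  block <- 1 + 2 * np^2
  if (length(toks) %% block != 0)
    stop("parse error: network data in ", path, " are not a whole number of ",
         np, "-port frequency blocks (wrong port count?)")
  nfreq <- length(toks) %/% block
  toks <- matrix(toks, nrow = block)
  freqs <- toks[1, ] * fscale
  S <- lapply(seq_len(nfreq), function(k) {
    v <- toks[-1, k]
    a <- v[seq(1, length(v), 2)]; b <- v[seq(2, length(v), 2)]
    z <- switch(fmt,
                RI = complex(real = a, imaginary = b),
                MA = a * exp(1i * b * pi / 180),
                DB = 10^(a / 20) * exp(1i * b * pi / 180))
    if (np == 2) matrix(z, 2, 2) else matrix(z, np, np, byrow = TRUE)
  })
  if (is.unsorted(freqs)) stop("parse error: frequencies not increasing in ", path)
  structure(list(freqs = freqs, S = S, scenario = scenario, noise = NULL,
                 provenance = "file", array = NULL),
            class = "measurement_set")
}

#' Write a measurement set as Touchstone v1 (RI, GHz)
#' @param ms a `measurement_set`
#' @param path output path ending in `.sNp` with N the antenna count
#' @export
write_touchstone <- function(ms, path) {
  np <- nrow(ms$S[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("! dbimtwist %d-port export, scenario=%s", np, ms$scenario),
               "# GHz S RI R 50"), con)
  for (k in seq_along(ms$freqs)) {
    Sk <- ms$S[[k]]
    if (np == 2) Sk <- t(Sk)  # 2-port Touchstone order quirk
    z <- as.vector(t(Sk))     # row-major element sequence
    vals <- as.vector(rbind(Re(z), Im(z)))
    rows <- split(vals, ceiling(seq_along(vals) / 8))
    rows[[1]] <- c(ms$freqs[k] / 1e9, rows[[1]])
    writeLines(vapply(rows, function(r) paste(sprintf("%.12g", r), collapse = " "), ""), con)
  }
  invisible(path)
}
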