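#' Simulate the "no target" baseline on the inversion model
#'
#' Runs the forward solver on an initial-guess phantom for every antenna and
#' returns a simulated `measurement_set`. This is the reference the
#' calibration uses to bring measured data onto the simulator's scale.
#'
#' @inheritParams multistatic_scan
#' @export
simulate_baseline <- function(ph, array, freqs, source_args = list(),
                              options = fdtd_options(), keep_fields = FALSE) {
  multistatic_scan(ph, array, freqs, scenario = "no_target",
                   source_args = source_args, options = options,
                   keep_fields = keep_fields)
}

#' Calibrate target/no-target measurements against a simulated baseline
#'
#' Converts a raw measurement pair into scattered-field data comparable with
#' the forward model. For each transmit-receive pair and frequency the
#' default `"ratio"` method computes
#' \deqn{E_{s,cal} = (S_t - S_{nt}) \cdot E_{sim,nt} / S_{nt},}
#' i.e. the difference signal rescaled by the ratio of simulated to measured
#' baseline, which cancels channel factors common to both measurements.
#' Entries with `|S_nt|` below `floor_rel` times the per-frequency maximum
#' are masked and excluded from the inversion data.
#'
#' @param target_ms,notarget_ms `measurement_set`s sharing frequencies/array
#' @param baseline_ms simulated baseline `measurement_set` (see
#'   [simulate_baseline()])
#' @param method `"ratio"` (default) or `"difference"` (no rescaling)
#' @param floor_rel relative magnitude floor for masking baseline entries
#' @param include_monostatic keep the i = j (transmit = receive) entries
#' @return object of class `calibrated_data`: per-frequency complex matrices
#'   with masked entries set to `NA`
#' @export
calibrate <- function(target_ms, notarget_ms, baseline_ms,
                      method = c("ratio", "difference"),
                      floor_rel = 1e-12, include_monostatic = TRUE) {
  method <- match.arg(method)
  for (ms in list(target_ms, notarget_ms, baseline_ms))
    stopifnot(inherits(ms, "measurement_set"))
  if (!isTRUE(all.equal(target_ms$freqs, notarget_ms$freqs)) ||
      !isTRUE(all.equal(target_ms$freqs, baseline_ms$freqs)))
    stop("frequency lists of the three measurement sets differ")
  M <- nrow(target_ms$S[[1]])
  if (nrow(notarget_ms$S[[1]]) != M || nrow(baseline_ms$S[[1]]) != M)
    stop("antenna counts of the three measurement sets differ")

  y <- vector("list", length(target_ms$freqs))
  for (k in seq_along(target_ms$freqs)) {
    St <- target_ms$S[[k]]; Snt <- notarget_ms$S[[k]]; Esim <- baseline_ms$S[[k]]
    bad <- abs(Snt) < floor_rel * max(abs(Snt))
    yk <- switch(method,
                 ratio = (St - Snt) * Esim / Snt,
                 difference = St - Snt)
    yk[bad] <- NA_complex_
    if (!include_monostatic) diag(yk) <- NA_complex_
    yk[!is.finite(Re(yk)) | !is.finite(Im(yk))] <- NA_complex_
    if (all(is.na(yk)))
      stop(sprintf("degenerate data: all entries masked at %.3g GHz",
                   target_ms$freqs[k] / 1e9))
    y[[k]] <- yk
  }
  structure(list(freqs = target_ms$freqs, y = y, method = method,
                 floor_rel = floor_rel, array = baseline_ms$array,
                 reference = list(target = target_ms$scenario,
                                  notarget = notarget_ms$scenario,
                                  baseline = baseline_ms$provenance)),
            class = "calibrated_data")
}

#' @export
print.calibrated_data <- function(x, ...) {
  cat(sprintf("Calibrated scattered-field data (%s method): %d frequencies, %d pairs/frequency, %d masked\n",
              x$method, length(x$freqs), length(x$y[[1]]),
              sum(vapply(x$y, function(m) sum(is.na(m)), 0L))))
  invisible(x)
}
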