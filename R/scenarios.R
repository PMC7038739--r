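#' Build a synthetic stroke-imaging scenario
#'
#' Assembles the ground-truth and initial-guess phantoms, the tissue models
#' and the antenna array for one virtual experiment, reproducing the
#' laboratory conditions: a 300 mm tank of 90% glycerol-water, a 153 x 112 mm
#' elliptical average-brain phantom (optionally wrapped in a 5 mm CSF shell),
#' a 30 mm circular stroke target placed towards the upper-right between
#' antennas 1 and 8, and an 8-antenna elliptical array. The ground truth is
#' rasterized on a finer grid than the inversion model (1 mm vs 2 mm by
#' default) so that inverting simulated data does not commit the inverse
#' crime. `scale` shrinks every length for reduced-size studies.
#'
#' @param target `"h"` (blood), `"i25"`, `"i50"` (ischaemic presets) or
#'   `"none"`
#' @param scale global geometric scale factor (1 = laboratory size)
#' @param csf_thickness CSF shell thickness before scaling, m (0 disables;
#'   the shell is present only in the ground truth, never in the guess)
#' @param drift relative increase of the brain background's dielectric
#'   constant between the "no target" and "target" measurements (gel-ageing
#'   drift; the measured day-6 increase was 10-15%)
#' @param spacing_true,spacing_guess absolute grid spacings, m (not scaled
#'   by `scale`: reduced-size studies keep the 1 mm data / 2 mm inversion
#'   grids of the full-size protocol)
#' @param lib a [tissue_library()]
#' @return list with `spec`, `truth_target`, `truth_notarget`, `guess`,
#'   `array`, `lib`, `target`
#' @export
stroke_scenario <- function(target = c("h", "i25", "i50", "none"),
                            scale = 1, csf_thickness = 0, drift = 0,
                            spacing_true = 0.001, spacing_guess = 0.002,
                            lib = tissue_library()) {
  target <- match.arg(target)
  spec <- scale_geometry(geometry_spec(csf_thickness = csf_thickness), scale)
  spec_guess <- scale_geometry(geometry_spec(csf_thickness = 0), scale)
  truth_nt <- build_head_phantom(spec, lib, spacing_true)
  truth_t <- truth_nt
  if (drift != 0) {
    truth_t <- perturb_phantom(truth_t, drift, "brain")
    if (csf_thickness > 0) truth_t <- perturb_phantom(truth_t, drift, "csf")
  }
  mat <- switch(target, h = lib$blood, i25 = lib$ischemia_25,
                i50 = lib$ischemia_50, none = NULL)
  if (!is.null(mat)) truth_t <- insert_stroke_target(truth_t, spec, mat)
  guess <- build_head_phantom(spec_guess, lib, spacing_guess)
  array <- array_geometry(spec_guess)
  list(spec = spec, truth_target = truth_t, truth_notarget = truth_nt,
       guess = guess, array = array, lib = lib, target = target)
}

#' Run a complete virtual stroke-imaging study
#'
#' Simulates the "target" and "no target" multistatic measurements on the
#' ground-truth phantom, calibrates them against a baseline simulated on the
#' initial-guess model, reconstructs with DBIM-TwIST over the frequency
#' schedule, and classifies the detected target.
#'
#' @param scenario a [stroke_scenario()]
#' @param freqs frequency schedule, Hz (ascending hopping order)
#' @param iterations DBIM iterations per frequency
#' @param noise_snr_db optional measurement SNR in dB
#' @param seed RNG seed for the noise draw
#' @param solver a [twist_params()]
#' @param options [fdtd_options()]
#' @param threshold detection/classification contrast threshold
#' @param verbose print per-iteration residuals
#' @return list with `result` (a `dbim`), `report` (a `detection_report`),
#'   `calibrated`, `target_ms`, `notarget_ms`
#' @export
run_stroke_study <- function(scenario, freqs = c(0.7e9, 1.1e9, 1.5e9),
                             iterations = 15, noise_snr_db = NULL, seed = NULL,
                             solver = twist_params(), options = fdtd_options(),
                             threshold = 0.1, verbose = FALSE) {
  freqs <- sort(as.numeric(freqs))
  tm <- multistatic_scan(scenario$truth_target, scenario$array, freqs,
                         scenario = "target", noise_snr_db = noise_snr_db,
                         seed = seed, options = options)
  nm <- multistatic_scan(scenario$truth_notarget, scenario$array, freqs,
                         scenario = "no_target", noise_snr_db = noise_snr_db,
                         seed = if (is.null(seed)) NULL else seed + 1,
                         options = options)
  base <- simulate_baseline(scenario$guess, scenario$array, freqs,
                            options = options)
  cal <- calibrate(tm, nm, base)
  res <- dbim_reconstruct(cal, scenario$guess, schedule = freqs,
                          iterations = iterations, solver = solver,
                          options = options, verbose = verbose)
  rep <- detection_report(res, threshold = threshold)
  list(result = res, report = rep, calibrated = cal,
       target_ms = tm, notarget_ms = nm)
}
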