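#' Phantom geometry specification
#'
#' Geometry of the imaging experiment: a cylindrical tank of matching liquid
#' holding an elliptical brain phantom (optionally wrapped in a thin CSF
#' shell) with a circular stroke-mimicking target. Defaults reproduce the
#' experimental testbed: 300 mm tank, brain ellipse with 153 x 112 mm axes,
#' 5 mm CSF shell, 30 mm target placed off-centre towards the upper-right
#' (between antennas 1 and 8). All lengths in metres; the origin is the tank
#' centre.
#'
#' @param tank_diameter tank diameter (m)
#' @param brain_semi_axes numeric length 2, brain ellipse semi-axes (m)
#' @param csf_thickness CSF shell thickness (m); 0 disables the shell
#' @param target_diameter stroke-target diameter (m)
#' @param target_centre numeric length 2 (m); `NULL` places the target midway
#'   between the brain centre and the ellipse boundary along the +x/+y diagonal
#' @return an object of class `geometry_spec`
#' @export
geometry_spec <- function(tank_diameter = 0.300,
                          brain_semi_axes = c(0.0765, 0.056),
                          csf_thickness = 0,
                          target_diameter = 0.030,
                          target_centre = NULL) {
  stopifnot(tank_diameter > 0, length(brain_semi_axes) == 2,
            all(brain_semi_axes > 0), csf_thickness >= 0, target_diameter > 0)
  a <- brain_semi_axes[1]; b <- brain_semi_axes[2]
  if (2 * max(a, b) >= tank_diameter)
    stop("geometry error: brain ellipse does not fit inside the tank")
  if (csf_thickness >= min(a, b))
    stop("geometry error: CSF shell thicker than the brain semi-axis")
  if (is.null(target_centre)) {
    s <- sqrt(2) * a * b / sqrt(a^2 + b^2)  # diagonal ray hits ellipse at |r|=s
    target_centre <- (s / 2) * c(1, 1) / sqrt(2)
  }
  spec <- structure(list(tank_diameter = tank_diameter,
                         brain_semi_axes = c(a, b),
                         csf_thickness = csf_thickness,
                         target_diameter = target_diameter,
                         target_centre = target_centre),
                    class = "geometry_spec")
  .check_target_inside(spec)
  spec
}

# target disc (with margin of one CSF thickness) must stay inside the brain
.check_target_inside <- function(spec) {
  a <- spec$brain_semi_axes[1] - spec$csf_thickness
  b <- spec$brain_semi_axes[2] - spec$csf_thickness
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  r <- spec$target_diameter / 2
  px <- spec$target_centre[1] + r * cos(th)
  py <- spec$target_centre[2] + r * sin(th)
  if (any((px / a)^2 + (py / b)^2 >= 1))
    stop("geometry error: target disc crosses the brain boundary")
  invisible(TRUE)
}

#' Uniformly rescale a geometry
#'
#' Convenience for reduced-size studies: scales every length (tank, brain
#' axes, CSF shell, target size and position) by one factor.
#' @param spec a [geometry_spec()]
#' @param scale positive scale factor
#' @export
scale_geometry <- function(spec, scale) {
  stopifnot(inherits(spec, "geometry_spec"), scale > 0)
  geometry_spec(spec$tank_diameter * scale, spec$brain_semi_axes * scale,
                spec$csf_thickness * scale, spec$target_diameter * scale,
                spec$target_centre * scale)
}

# region label codes
.LBL <- c(tank = 0L, brain = 1L, csf = 2L, target = 3L)

#' Rasterize the head phantom onto a regular grid
#'
#' Builds the gridded ground-truth (or initial-guess) map of Debye parameters.
#' The grid covers the square circumscribing the tank; cell (i, j) has its
#' centre at `(-R + (i - 1/2) * spacing, -R + (j - 1/2) * spacing)` and every
#' cell is assigned by a centre-point membership test: matching medium outside
#' the brain ellipse, a CSF ring of the stated thickness when enabled, brain
#' inside.
#'
#' @param spec a [geometry_spec()]
#' @param lib a [tissue_library()]
#' @param spacing grid spacing (m); must resolve the tank with >= 50 cells
#' @return an object of class `phantom_map` holding matrices `eps_inf`,
#'   `delta_eps`, `sigma_s`, `tau` and integer `label`
#' @export
build_head_phantom <- function(spec, lib = tissue_library(), spacing = 0.002) {
  stopifnot(inherits(spec, "geometry_spec"))
  n <- round(spec$tank_diameter / spacing)
  if (n < 50) stop("geometry error: spacing too coarse (< 50 cells across tank)")
  R <- spec$tank_diameter / 2
  xc <- -R + (seq_len(n) - 0.5) * spacing
  X <- matrix(xc, n, n)
  Y <- matrix(xc, n, n, byrow = TRUE)
  a <- spec$brain_semi_axes[1]; b <- spec$brain_semi_axes[2]
  lab <- matrix(.LBL[["tank"]], n, n)
  inside <- (X / a)^2 + (Y / b)^2 < 1
  if (spec$csf_thickness > 0) {
    ai <- a - spec$csf_thickness; bi <- b - spec$csf_thickness
    inner <- (X / ai)^2 + (Y / bi)^2 < 1
    lab[inside & !inner] <- .LBL[["csf"]]
    lab[inner] <- .LBL[["brain"]]
  } else {
    lab[inside] <- .LBL[["brain"]]
  }
  ph <- structure(list(spacing = spacing, n = n, origin = c(-R, -R),
                       eps_inf = matrix(NA_real_, n, n),
                       delta_eps = matrix(NA_real_, n, n),
                       sigma_s = matrix(NA_real_, n, n),
                       tau = matrix(NA_real_, n, n),
                       label = lab, spec = spec),
                  class = "phantom_map")
  ph <- .assign_material(ph, .LBL[["tank"]], lib$glycerol90)
  ph <- .assign_material(ph, .LBL[["brain"]], lib$brain)
  if (spec$csf_thickness > 0) ph <- .assign_material(ph, .LBL[["csf"]], lib$csf)
  ph
}

.assign_material <- function(ph, code, model) {
  sel <- ph$label == code
  ph$eps_inf[sel] <- model$eps_inf
  ph$delta_eps[sel] <- model$delta_eps
  ph$sigma_s[sel] <- model$sigma_s
  ph$tau[sel] <- model$tau
  ph
}

#' Cell-centre coordinates of a phantom grid
#' @param ph a `phantom_map`
#' @return list with vectors `x`, `y` (m)
#' @export
phantom_coords <- function(ph) {
  x <- ph$origin[1] + (seq_len(ph$n) - 0.5) * ph$spacing
  list(x = x, y = x - ph$origin[1] + ph$origin[2])
}

#' Insert the circular stroke target
#'
#' Re-assigns cells within the target disc to the given material and the
#' `target` region label; all other cells are untouched.
#'
#' @param ph a `phantom_map`
#' @param spec the [geometry_spec()] giving target centre/diameter
#' @param material a [debye_model()] (e.g. `tissue_library()$blood`)
#' @export
insert_stroke_target <- function(ph, spec, material) {
  stopifnot(inherits(ph, "phantom_map"), inherits(spec, "geometry_spec"),
            inherits(material, "debye_model"))
  .check_target_inside(spec)
  co <- phantom_coords(ph)
  X <- matrix(co$x, ph$n, ph$n); Y <- matrix(co$y, ph$n, ph$n, byrow = TRUE)
  r <- spec$target_diameter / 2
  disc <- (X - spec$target_centre[1])^2 + (Y - spec$target_centre[2])^2 < r^2
  if (any(disc & ph$label == .LBL[["tank"]]))
    stop("geometry error: target disc extends outside the brain region")
  ph$label[disc] <- .LBL[["target"]]
  .assign_material(ph, .LBL[["target"]], material)
}

#' Scale the dielectric properties of one labelled region
#'
#' Applies the [scale_contrast()] transformation cell-wise to every cell of
#' the named region, emulating background-property drift of the gel phantom
#' over time (the measured day-6 vs day-1 increase of 10-15%).
#'
#' @param ph a `phantom_map`
#' @param scale relative change of real permittivity at `ref_freq` (> -1)
#' @param region one of `"tank"`, `"brain"`, `"csf"`, `"target"`
#' @param ref_freq reference frequency, Hz
#' @export
perturb_phantom <- function(ph, scale, region = "brain", ref_freq = 1e9) {
  stopifnot(inherits(ph, "phantom_map"))
  if (scale <= -1) stop("scale must be > -1")
  if (!region %in% names(.LBL)) stop("unknown region label: ", region)
  sel <- ph$label == .LBL[[region]]
  if (scale == 0 || !any(sel)) return(ph)
  w <- 2 * pi * ref_freq
  er <- ph$eps_inf[sel] + ph$delta_eps[sel] / (1 + (w * ph$tau[sel])^2)
  g <- ((1 + scale) * er - 1) / (er - 1)
  if (any(g < 0)) stop("scale drives eps_inf below 1")
  ph$eps_inf[sel] <- 1 + g * (ph$eps_inf[sel] - 1)
  ph$delta_eps[sel] <- g * ph$delta_eps[sel]
  ph$sigma_s[sel] <- g * ph$sigma_s[sel]
  ph
}

#' Complex permittivity image of a phantom at one frequency
#' @param ph a `phantom_map`
#' @param freq frequency, Hz
#' @return complex matrix
#' @export
phantom_permittivity <- function(ph, freq) {
  w <- 2 * pi * freq
  ph$eps_inf + ph$delta_eps / (1 + 1i * w * ph$tau) + ph$sigma_s / (1i * w * .eps0)
}

#' @export
print.phantom_map <- function(x, ...) {
  cnt <- table(factor(x$label, levels = .LBL, labels = names(.LBL)))
  cat(sprintf("Head phantom: %d x %d cells at %.3g mm spacing\n",
              x$n, x$n, x$spacing * 1e3))
  cat("  region cells:", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.phantom_map <- function(x, freq = 1e9, part = c("real", "imag"), ...) {
  part <- match.arg(part)
  eps <- phantom_permittivity(x, freq)
  img <- if (part == "real") Re(eps) else -Im(eps)
  co <- phantom_coords(x)
  graphics::image(co$x * 1e3, co$y * 1e3, img, asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("%s(eps) at %.2f GHz", part, freq / 1e9), ...)
  invisible(x)
}
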