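#' Optical parameters of a light field microscope
#'
#' Bundles the quantities needed to relate the refocusing shear parameter
#' \eqn{\alpha} to physical depth: the microlens subimage pitch in camera
#' pixels \eqn{P}, the microlens focal length \eqn{F}, and the transverse
#' magnification \eqn{M}, via \deqn{\Delta z = P (1 - 1/\alpha) F / M^2.}
#'
#' @param pitch_px Subimage pitch in camera pixels (positive, > 1).
#' @param mla_focal_um Microlens array focal length in micrometres.
#' @param magnification Transverse magnification of the microscope.
#' @param pixel_size_um Camera pixel size in micrometres.
#' @param frame_rate_hz Acquisition frame rate in Hz.
#' @param aperture_radius_frac Fraction of half the pitch defining the radius
#'   of the valid (illuminated) circular region within each square subimage.
#'   Corners of the square tiles receive no light in the real instrument.
#'
#' @return An object of class `lf_optics`.
#' @export
#' @examples
#' opt <- lf_optics(pitch_px = 20, mla_focal_um = 2500, magnification = 10)
#' shear_to_depth(2, opt) # 250 um
lf_optics <- function(pitch_px = 19,
                      mla_focal_um = 6500,
                      magnification = 10,
                      pixel_size_um = 6.5,
                      frame_rate_hz = 20,
                      aperture_radius_frac = 0.95) {
  stopifnot(
    is.numeric(pitch_px), pitch_px > 1,
    mla_focal_um > 0, magnification > 0, pixel_size_um > 0,
    frame_rate_hz > 0,
    aperture_radius_frac > 0, aperture_radius_frac <= 1
  )
  structure(
    list(
      pitch_px = pitch_px,
      mla_focal_um = mla_focal_um,
      magnification = magnification,
      pixel_size_um = pixel_size_um,
      frame_rate_hz = frame_rate_hz,
      aperture_radius_frac = aperture_radius_frac
    ),
    class = "lf_optics"
  )
}

#' @export
print.lf_optics <- function(x, ...) {
  cat("<lf_optics>\n")
  cat(sprintf("  pitch:          %.3f px\n", x$pitch_px))
  cat(sprintf("  MLA focal:      %.1f um\n", x$mla_focal_um))
  cat(sprintf("  magnification:  %.2fx\n", x$magnification))
  cat(sprintf("  pixel size:     %.2f um\n", x$pixel_size_um))
  cat(sprintf("  frame rate:     %.1f Hz\n", x$frame_rate_hz))
  cat(sprintf("  aperture frac:  %.2f\n", x$aperture_radius_frac))
  cat(sprintf("  depth limit:    %.1f um (alpha -> Inf)\n", depth_limit(x)))
  invisible(x)
}

#' Object-space spacing of one spatial (microlens) sample, in micrometres.
#' @param optics An [lf_optics()] object.
#' @return Sample pitch in micrometres in the object plane.
#' @export
sample_pitch_um <- function(optics) {
  optics$pitch_px * optics$pixel_size_um / optics$magnification
}

#' Largest depth reachable by refocusing (the alpha -> Inf limit)
#' @param optics An [lf_optics()] object.
#' @return Depth in micrometres; depths at or beyond this are unreachable.
#' @export
depth_limit <- function(optics) {
  optics$pitch_px * optics$mla_focal_um / optics$magnification^2
}

#' Convert a refocusing shear parameter to depth
#'
#' \eqn{\Delta z = P (1 - 1/\alpha) F / M^2}. `alpha = 1` corresponds to the
#' native object plane (`dz = 0`), `alpha > 1` to planes beyond it.
#'
#' @param alpha Shear parameter(s), strictly positive.
#' @param optics An [lf_optics()] object.
#' @return Depth(s) in micrometres.
#' @export
shear_to_depth <- function(alpha, optics) {
  stopifnot(inherits(optics, "lf_optics"))
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("`alpha` must be strictly positive and finite")
  }
  optics$pitch_px * (1 - 1 / alpha) * optics$mla_focal_um /
    optics$magnification^2
}

#' Convert a depth to the refocusing shear parameter
#'
#' Inverse of [shear_to_depth()]; defined for depths below the reachable
#' limit \eqn{P F / M^2}.
#'
#' @param dz_um Depth(s) in micrometres.
#' @param optics An [lf_optics()] object.
#' @return Shear parameter(s) `alpha`.
#' @export
depth_to_shear <- function(dz_um, optics) {
  stopifnot(inherits(optics, "lf_optics"))
  lim <- depth_limit(optics)
  if (any(dz_um >= lim)) {
    stop(sprintf("depth >= %.1f um is unreachable for these optics", lim))
  }
  1 / (1 - dz_um / lim)
}

#' Construct a depth sweep for refocusing
#'
#' A strictly monotone ladder of shear parameters and their corresponding
#' depths, spaced uniformly in depth over `[zmin_um, zmax_um]`. Uniform depth
#' spacing makes the discrete depth labels of the cue responses and the MRF
#' equidistant in micrometres.
#'
#' @param optics An [lf_optics()] object.
#' @param zmin_um,zmax_um Depth range in micrometres.
#' @param steps Number of sweep points (default 256).
#' @return An object of class `depth_sweep` with fields `alphas`, `depths_um`.
#' @export
depth_sweep <- function(optics, zmin_um = -1000, zmax_um = 1000, steps = 256) {
  stopifnot(inherits(optics, "lf_optics"), zmax_um > zmin_um, steps >= 1)
  depths <- seq(zmin_um, zmax_um, length.out = steps)
  alphas <- depth_to_shear(depths, optics)
  structure(
    list(alphas = alphas, depths_um = depths, optics = optics),
    class = "depth_sweep"
  )
}

#' @export
print.depth_sweep <- function(x, ...) {
  cat(sprintf(
    "<depth_sweep> %d steps, %.1f .. %.1f um (alpha %.4f .. %.4f)\n",
    length(x$alphas), min(x$depths_um), max(x$depths_um),
    min(x$alphas), max(x$alphas)
  ))
  invisible(x)
}
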