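#' Construct a 4D light field
#'
#' The central container of the reconstruction pipeline: radiance
#' \eqn{L(x, y, u, v)} where \eqn{(x, y)} index microlenses (spatial samples)
#' and \eqn{(u, v)} index pixels within a subimage (angular samples, centred
#' so that \eqn{(0, 0)} is the chief ray / on-axis view). Angular samples
#' outside an inscribed circle of radius `aperture_radius_frac * n_u / 2`
#' receive no light in the instrument and are masked invalid.
#'
#' @param radiance 4D numeric array with dims `(n_x, n_y, n_u, n_v)`;
#'   nonnegative (NA marks invalid samples, e.g. sheared out of field).
#' @param optics An [lf_optics()] object.
#' @param angular_mask Optional `n_u x n_v` logical matrix of valid angular
#'   samples; defaults to the inscribed circular aperture.
#' @return An object of class `light_field`.
#' @export
light_field <- function(radiance, optics, angular_mask = NULL) {
  stopifnot(is.array(radiance), length(dim(radiance)) == 4)
  stopifnot(inherits(optics, "lf_optics"))
  d <- dim(radiance)
  if (d[3] != d[4]) {
    stop("angular dims must be square (n_u = n_v)")
  }
  if (any(radiance < 0, na.rm = TRUE)) {
    stop("radiance must be nonnegative")
  }
  if (is.null(angular_mask)) {
    uc <- centred_coords(d[3])
    vc <- centred_coords(d[4])
    rad <- optics$aperture_radius_frac * d[3] / 2
    angular_mask <- outer(uc^2, vc^2, `+`) <= rad^2
  }
  stopifnot(identical(dim(angular_mask), d[3:4]))
  structure(
    list(radiance = radiance, angular_mask = angular_mask, optics = optics),
    class = "light_field"
  )
}

#' @export
print.light_field <- function(x, ...) {
  d <- dim(x$radiance)
  cat(sprintf(
    "<light_field> %d x %d spatial, %d x %d angular (%d valid views)\n",
    d[1], d[2], d[3], d[4], sum(x$angular_mask)
  ))
  invisible(x)
}

#' @export
dim.light_field <- function(x) dim(x$radiance)

# Centred angular pixel coordinates of a light field.
angular_coords <- function(lf) {
  d <- dim(lf$radiance)
  list(u = centred_coords(d[3]), v = centred_coords(d[4]))
}

#' Flat-field (vignetting) correction of a raw mosaic
#'
#' Divides a raw light field mosaic by a background image captured under
#' identical illumination, correcting the radial fall-off of detected
#' radiance for off-axis rays. Pixels whose background falls below `floor`
#' (relative to the background maximum) are set to 0 and reported via the
#' `"flagged"` attribute.
#'
#' @param raw,background Numeric matrices of identical shape.
#' @param floor Relative background floor below which pixels are zeroed.
#' @return Corrected matrix with attribute `flagged` (logical matrix).
#' @export
correct_vignetting <- function(raw, background, floor = 1e-3) {
  if (!identical(dim(raw), dim(background))) {
    stop("`raw` and `background` must have the same shape")
  }
  if (all(background <= 0)) {
    stop("background is all zero")
  }
  lo <- floor * max(background)
  bad <- background < lo
  out <- raw / pmax(background, lo)
  out[bad] <- 0
  attr(out, "flagged") <- bad
  out
}

#' Extract a perspective (pinhole) view
#'
#' Selecting the same centred angular pixel `(u, v)` from each subimage
#' yields a perspective view of the object; `pinhole_view(lf, 0, 0)` is the
#' on-axis view used for segmentation.
#'
#' @param lf A [light_field()].
#' @param u,v Centred angular coordinates (integers; 0 = chief ray).
#' @return `n_x x n_y` numeric matrix.
#' @export
pinhole_view <- function(lf, u = 0, v = 0) {
  ac <- angular_coords(lf)
  iu <- match(u, ac$u)
  iv <- match(v, ac$v)
  if (is.na(iu) || is.na(iv) || !lf$angular_mask[iu, iv]) {
    stop("(u, v) outside the valid angular aperture")
  }
  lf$radiance[, , iu, iv]
}

#' Computationally refocus a light field
#'
#' Shears the light field parallel to the (x, y) plane,
#' \deqn{L_\alpha(x,y,u,v) = L_o(u(1-1/\alpha)+x/\alpha,\ v(1-1/\alpha)+y/\alpha,\ u,v),}
#' simulating an axial shift of the sample by
#' \eqn{\Delta z = P(1-1/\alpha)F/M^2}. Bilinear interpolation in (x, y),
#' coordinates centred on the optical axis; samples sheared outside the
#' spatial extent become NA so that view integration can renormalise.
#'
#' @param lf A [light_field()].
#' @param alpha Shear parameter (> 0); `refocus(lf, 1)` returns `lf`.
#' @param interp Interpolation for the shear: Catmull-Rom `"cubic"`
#'   (default; exact at integer shifts, low interpolation blur) or
#'   `"bilinear"`.
#' @return A refocused [light_field()].
#' @export
refocus <- function(lf, alpha, interp = c("cubic", "bilinear")) {
  stopifnot(inherits(lf, "light_field"))
  interp <- match.arg(interp)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be strictly positive")
  }
  ac <- angular_coords(lf)
  rad <- lf_refocus_cpp(
    lf$radiance, dim(lf$radiance), alpha,
    ac$u, ac$v, lf$angular_mask, if (interp == "cubic") 1L else 0L
  )
  out <- lf
  out$radiance <- rad
  out
}

#' Integrate a light field over its angular aperture
#'
#' The per-pixel mean over valid angular samples,
#' \eqn{\bar L(x,y) = \sum_{(u,v)} L(x,y,u,v) / N(x,y)}: an image focused at
#' the plane selected by any preceding [refocus()]. Using the mean rather
#' than the sum makes renormalisation at sheared-out edges automatic.
#'
#' @param lf A [light_field()].
#' @return `n_x x n_y` matrix with attribute `n_valid` (contributing sample
#'   counts); pixels with zero valid samples are 0 there and flagged NA-free.
#' @export
integrate_views <- function(lf) {
  stopifnot(inherits(lf, "light_field"))
  d <- dim(lf$radiance)
  m <- matrix(lf$radiance, d[1] * d[2], d[3] * d[4])
  m <- m[, as.vector(lf$angular_mask), drop = FALSE]
  cnt <- rowSums(is.finite(m))
  s <- rowSums(m, na.rm = TRUE)
  out <- matrix(ifelse(cnt > 0, s / pmax(cnt, 1), 0), d[1], d[2])
  attr(out, "n_valid") <- matrix(cnt, d[1], d[2])
  out
}

#' Compute a focal stack (z-stack) from a single exposure
#'
#' `stack[, , k] = integrate_views(refocus(lf, alpha_k))` for every sweep
#' point, ordered by depth.
#'
#' @param lf A [light_field()].
#' @param sweep A [depth_sweep()].
#' @return 3D array `(n_x, n_y, steps)` with attribute `depths_um`.
#' @export
focal_stack <- function(lf, sweep) {
  stopifnot(inherits(lf, "light_field"), inherits(sweep, "depth_sweep"))
  if (length(sweep$alphas) < 1) {
    stop("empty sweep")
  }
  st <- lf_sweep_stats(lf, sweep$alphas)
  out <- st$sum / pmax(st$count, 1)
  out[st$count == 0] <- 0
  attr(out, "depths_um") <- sweep$depths_um
  out
}

# One pass over the sweep returning per-alpha angular sum, sum of squares
# and valid-sample count (nx x ny x n_alpha arrays).
lf_sweep_stats <- function(lf, alphas, interp = "cubic",
                           object_frame = FALSE) {
  ac <- angular_coords(lf)
  lf_sweep_stats_cpp(
    lf$radiance, dim(lf$radiance), alphas,
    ac$u, ac$v, lf$angular_mask, if (interp == "cubic") 1L else 0L,
    object_frame
  )
}
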