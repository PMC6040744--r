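#' Parameters of the synthetic worm locomotion model
#'
#' The generator drives a 25-segment body with a travelling undulation wave
#' whose oscillation plane rolls slowly about the body axis: tangent angle
#' \eqn{\psi(s, t) = A \sin(2\pi s/\lambda - 2\pi f t)} applied in a plane
#' rotated by the roll phase \eqn{\chi(t) = 2\pi (f/k) t}, so the worm
#' completes `roll_ratio` undulation cycles per full body roll. Tangents are
#' integrated with fixed segment lengths into 3D coordinates and the
#' centroid advances at `speed_um_s`.
#'
#' @param body_length_um Total body length (micrometres).
#' @param n_segments Number of midline segments (25 gives 26 points).
#' @param amplitude_rad Undulation amplitude of the tangent angle (radians).
#' @param wavelength_bl Undulation wavelength in body lengths.
#' @param frequency_hz Undulation frequency (Hz).
#' @param roll_ratio Undulation cycles per body-roll cycle (`Inf` = planar).
#' @param speed_um_s Translation speed of the centroid (micrometres/s).
#' @param angle_noise_rad SD of iid Gaussian noise added to the tangent
#'   angle per segment and frame (radians).
#' @param seed Integer seed; fixes the output exactly.
#' @return An object of class `locomotion_params`.
#' @export
locomotion_params <- function(body_length_um = 1000,
                              n_segments = 25,
                              amplitude_rad = 0.6,
                              wavelength_bl = 1.5,
                              frequency_hz = 1,
                              roll_ratio = 8.5,
                              speed_um_s = 50,
                              angle_noise_rad = 0.05,
                              seed = 7) {
  stopifnot(
    body_length_um > 0, n_segments >= 3, amplitude_rad >= 0,
    wavelength_bl > 0, frequency_hz > 0, roll_ratio > 0,
    speed_um_s >= 0, angle_noise_rad >= 0
  )
  structure(
    list(
      body_length_um = body_length_um, n_segments = n_segments,
      amplitude_rad = amplitude_rad, wavelength_bl = wavelength_bl,
      frequency_hz = frequency_hz, roll_ratio = roll_ratio,
      speed_um_s = speed_um_s, angle_noise_rad = angle_noise_rad,
      seed = seed
    ),
    class = "locomotion_params"
  )
}

#' Generate ground-truthed 3D worm locomotion
#'
#' @param params A [locomotion_params()].
#' @param n_frames Number of frames.
#' @param dt_s Frame interval in seconds.
#' @return List with `skeletons` (tibble: frame, time_s, point, x_um, y_um,
#'   z_um), `angles` (tibble: frame, segment, theta, phi; mean-zeroed truth)
#'   and `params`.
#' @export
generate_locomotion <- function(params, n_frames = 200, dt_s = 0.05) {
  stopifnot(inherits(params, "locomotion_params"), n_frames >= 1, dt_s > 0)
  p <- params
  set.seed(p$seed)
  ns <- p$n_segments
  seg_len <- p$body_length_um / ns
  s_frac <- (seq_len(ns) - 0.5) / ns
  frames <- vector("list", n_frames)
  angles <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    t <- (f - 1) * dt_s
    psi <- p$amplitude_rad *
      sin(2 * pi * s_frac / p$wavelength_bl - 2 * pi * p$frequency_hz * t)
    if (p$angle_noise_rad > 0) {
      psi <- psi + rnorm(ns, sd = p$angle_noise_rad)
    }
    chi <- if (is.finite(p$roll_ratio)) {
      2 * pi * (p$frequency_hz / p$roll_ratio) * t
    } else {
      0
    }
    tx <- cos(psi)
    ty <- sin(psi) * cos(chi)
    tz <- sin(psi) * sin(chi)
    pts <- rbind(c(0, 0, 0), apply(cbind(tx, ty, tz) * seg_len, 2, cumsum))
    pts[, 1] <- pts[, 1] - mean(pts[, 1]) + p$speed_um_s * t
    pts[, 2] <- pts[, 2] - mean(pts[, 2])
    pts[, 3] <- pts[, 3] - mean(pts[, 3])
    theta <- unwrap_angles(atan2(ty, tx))
    phi <- asin(pmin(pmax(tz, -1), 1))
    frames[[f]] <- tibble::tibble(
      frame = f, time_s = t, point = seq_len(ns + 1) - 1,
      x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3]
    )
    angles[[f]] <- tibble::tibble(
      frame = f, segment = seq_len(ns),
      theta = theta - mean(theta), phi = phi - mean(phi)
    )
  }
  list(
    skeletons = dplyr::bind_rows(frames),
    angles = dplyr::bind_rows(angles),
    params = p
  )
}

# Remove 2*pi jumps from an angle sequence along the body.
unwrap_angles <- function(a) {
  if (length(a) < 2) {
    return(a)
  }
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  a[1] + c(0, cumsum(d))
}

#' Rendering configuration for the synthetic light field microscope
#'
#' @param optics An [lf_optics()]; `pitch_px` must be a whole number (the
#'   renderer tiles an integer lattice; rotated/non-integer mosaics for
#'   rectification tests are made with [render_lattice_mosaic()]).
#' @param n_lenses Number of microlenses per side of the square mosaic.
#' @param peak_signal Object signal scale in counts.
#' @param background_level Uniform illumination level in counts.
#' @param noise_sd SD of additive Gaussian read noise in counts.
#' @param vignette_strength Quadratic radial fall-off within each subimage
#'   (0 = none, 1 = zero at the aperture edge).
#' @return An object of class `render_config`.
#' @export
render_config <- function(optics = lf_optics(),
                          n_lenses = 26,
                          peak_signal = 1000,
                          background_level = 100,
                          noise_sd = 0,
                          vignette_strength = 0.5) {
  stopifnot(inherits(optics, "lf_optics"))
  if (abs(optics$pitch_px - round(optics$pitch_px)) > 1e-9) {
    stop("renderer requires an integer pitch")
  }
  stopifnot(
    n_lenses >= 4, peak_signal > 0, background_level >= 0,
    noise_sd >= 0, vignette_strength >= 0, vignette_strength <= 1
  )
  structure(
    list(
      optics = optics, n_lenses = n_lenses, peak_signal = peak_signal,
      background_level = background_level, noise_sd = noise_sd,
      vignette_strength = vignette_strength
    ),
    class = "render_config"
  )
}

#' Render a worm body into a ground-truthed scene
#'
#' The body is a tube swept along the midline (radius optionally tapered
#' towards head and tail). For every spatial sample the intensity is the
#' chord length of the optical column through the tube — so the recorded
#' depth truth mirrors a contrast-weighted average over the worm thickness —
#' and the depth is the axial position of the nearest midline point.
#'
#' @param skeleton Matrix or data frame with columns x_um, y_um, z_um (any
#'   number of ordered midline points; they are densely resampled).
#' @param cfg A [render_config()]; fixes the scene grid (`n_lenses` square,
#'   one sample per microlens, centred on the optical axis).
#' @param radius_um Maximal body radius in micrometres.
#' @param taper Taper the radius towards the ends (elliptical profile)?
#' @param texture_amp Amplitude of the multiplicative band-limited texture
#'   emulating DIC body contrast (0 disables). Without texture a uniform
#'   tube carries depth information only at its edges.
#' @param texture_scale Correlation length of the texture in samples.
#' @param texture_seed Seed of the (deterministic) texture pattern.
#' @param blur_sigma Gaussian pre-blur of the scene in samples, emulating
#'   the in-focus optical PSF.
#' @param supersample Rendering-grid oversampling factor relative to the
#'   microlens grid; views are splatted on the fine grid and block-averaged,
#'   so rendered views closely approximate exact samples of a continuous
#'   scene.
#' @return An object of class `scene_truth`: `intensity` (normalised to 1),
#'   `depth_um` (NA outside), `footprint`, `skeleton_um`, `cfg`.
#' @export
render_worm_scene <- function(skeleton, cfg, radius_um = 40, taper = TRUE,
                              texture_amp = 0.4, texture_scale = 2,
                              texture_seed = 99, blur_sigma = 0.5,
                              supersample = 8) {
  stopifnot(inherits(cfg, "render_config"), supersample >= 1)
  sk <- as.matrix(as.data.frame(skeleton)[, c("x_um", "y_um", "z_um")])
  pitch_um <- sample_pitch_um(cfg$optics)
  n <- cfg$n_lenses
  ss <- as.integer(supersample)
  # dense midline resampling (linear, ~1/3 of the fine sample spacing)
  seg <- sqrt(rowSums(diff(sk)^2))
  s <- c(0, cumsum(seg))
  if (max(s) == 0) stop("degenerate skeleton")
  sd_ <- seq(0, max(s), by = max(pitch_um / (3 * ss), max(s) / 4000))
  dense <- vapply(
    1:3, function(k) approx(s, sk[, k], xout = sd_)$y,
    numeric(length(sd_))
  )
  sf <- sd_ / max(s)
  r_prof <- if (taper) radius_um * sqrt(pmax(4 * sf * (1 - sf), 0)) else {
    rep(radius_um, length(sf))
  }
  half_fov <- (n - 1) / 2 * pitch_um
  if (any(abs(dense[, 1:2]) > half_fov + radius_um)) {
    stop("worm outside the rendered field of view")
  }
  # coarse rasterization: ground truth on the microlens grid
  truth <- rasterize_tube(dense, r_prof, n, pitch_um)
  inside <- truth$inside
  depth <- ifelse(inside, truth$z, NA_real_)
  # fine rasterization: rendering grid (supersampled), with texture and PSF
  fine <- rasterize_tube(dense, r_prof, n * ss, pitch_um / ss)
  fint <- fine$chord / (2 * radius_um)
  # EBImage's Gaussian brush must fit inside the image; cap sigma on
  # small mosaics
  gblur_safe <- function(img, sigma) {
    sig <- min(sigma, (min(dim(img)) - 2) / 7)
    if (sig <= 0) {
      return(img)
    }
    EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sig))
  }
  if (texture_amp > 0) {
    rs <- get0(".Random.seed", envir = globalenv())
    set.seed(texture_seed)
    tex <- matrix(rnorm((n * ss)^2), n * ss, n * ss)
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
    tex <- gblur_safe(tex, texture_scale * ss)
    tex <- tex / sd(tex)
    fint <- fint * pmax(1 + texture_amp * tex, 0.1)
  }
  if (blur_sigma > 0) {
    fint <- pmax(gblur_safe(fint, blur_sigma * ss), 0)
  }
  block_mean <- function(m) {
    if (ss == 1) {
      return(m)
    }
    m2 <- array(m, dim = c(ss, n, ss, n))
    apply(m2, c(2, 4), mean)
  }
  structure(
    list(
      intensity = block_mean(fint), depth_um = depth, footprint = inside,
      skeleton_um = sk, cfg = cfg,
      fine = list(
        intensity = fint,
        # nearest-midline depth everywhere: PSF tails just outside the
        # footprint shear with the adjacent body rather than staying at
        # the native plane
        depth_um = fine$z,
        supersample = ss
      )
    ),
    class = "scene_truth"
  )
}

# Windowed tube rasterizer: for each grid sample, the nearest dense midline
# point (by penetration depth r^2 - d^2), giving chord length, axial
# position and footprint membership. Grid is n x n, centred, `pitch` um per
# sample.
rasterize_tube <- function(dense, r_prof, n, pitch) {
  best_pen <- matrix(-Inf, n, n)
  best_d2 <- matrix(Inf, n, n)
  best_z <- matrix(0, n, n)
  best_r <- matrix(0, n, n)
  ctr <- (n - 1) / 2
  coords <- centred_coords(n) * pitch
  for (i in seq_len(nrow(dense))) {
    r <- r_prof[i]
    ci <- dense[i, 1] / pitch + ctr + 1
    cj <- dense[i, 2] / pitch + ctr + 1
    w <- ceiling((r + pitch) / pitch) + 1
    i0 <- max(1, floor(ci - w))
    i1 <- min(n, ceiling(ci + w))
    j0 <- max(1, floor(cj - w))
    j1 <- min(n, ceiling(cj + w))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1
    jj <- j0:j1
    d2 <- outer((coords[ii] - dense[i, 1])^2, (coords[jj] - dense[i, 2])^2, `+`)
    pen <- r^2 - d2
    upd <- pen > best_pen[ii, jj]
    if (any(upd)) {
      sub <- function(m) m[ii, jj]
      bp <- sub(best_pen)
      bd <- sub(best_d2)
      bz <- sub(best_z)
      br <- sub(best_r)
      bp[upd] <- pen[upd]
      bd[upd] <- d2[upd]
      bz[upd] <- dense[i, 3]
      br[upd] <- r
      best_pen[ii, jj] <- bp
      best_d2[ii, jj] <- bd
      best_z[ii, jj] <- bz
      best_r[ii, jj] <- br
    }
  }
  inside <- best_pen > 0
  chord <- matrix(0, n, n)
  chord[inside] <- 2 * sqrt(best_pen[inside])
  list(inside = inside, chord = chord, z = best_z)
}

#' Render a scene into a raw light field mosaic
#'
#' For each valid angular sample (u, v), scene content at depth
#' \eqn{\Delta z} is splatted with a lateral shift of
#' \eqn{(1 - 1/\alpha(\Delta z)) (u, v)} spatial samples, where
#' \eqn{\alpha(\Delta z)} inverts the shear-depth relation — rendering is
#' the exact adjoint of the refocus shear. Per-subimage vignetting, a
#' uniform illumination level and Gaussian read noise are then applied and
#' the views tiled into a mosaic.
#'
#' @param scene A [render_worm_scene()] result (or compatible list).
#' @param cfg A [render_config()] (defaults to `scene$cfg`).
#' @param seed Integer seed for the read noise (NULL = no reseeding).
#' @return List: `mosaic` (raw counts), `background` (noise-free flat-field
#'   mosaic), `lf_truth` (noise-free, unvignetted [light_field()] of the
#'   object signal), `scene`.
#' @export
render_light_field <- function(scene, cfg = scene$cfg, seed = NULL) {
  stopifnot(inherits(cfg, "render_config"))
  opt <- cfg$optics
  n <- cfg$n_lenses
  np <- round(opt$pitch_px)
  lim <- depth_limit(opt)
  if (any(scene$depth_um >= lim, na.rm = TRUE)) {
    stop("scene depth unreachable for these optics")
  }
  fine <- scene$fine %||% list(
    intensity = scene$intensity,
    depth_um = ifelse(is.finite(scene$depth_um), scene$depth_um, 0),
    supersample = 1L
  )
  ss <- fine$supersample
  shear <- matrix(0, dim(fine$intensity)[1], dim(fine$intensity)[2])
  lit <- fine$intensity > 0
  shear[lit] <- 1 - 1 / depth_to_shear(fine$depth_um[lit], opt)
  signal <- fine$intensity * cfg$peak_signal
  uc <- centred_coords(np)
  radius <- opt$aperture_radius_frac * np / 2
  angmask <- outer(uc^2, uc^2, `+`) <= radius^2
  vig <- 1 - cfg$vignette_strength * outer(uc^2, uc^2, `+`) / radius^2
  vig <- pmax(vig, 0) * angmask
  block_mean <- function(m) {
    if (ss == 1) {
      return(m)
    }
    apply(array(m, dim = c(ss, n, ss, n)), c(2, 4), mean)
  }
  L <- array(0, dim = c(n, n, np, np))
  for (iv in seq_len(np)) {
    for (iu in seq_len(np)) {
      if (!angmask[iu, iv]) next
      # shifts are in microlens samples: ss fine pixels per sample
      L[, , iu, iv] <- block_mean(
        lf_splat_view_cpp(signal, shear * ss, uc[iu], uc[iv])
      )
    }
  }
  if (!is.null(seed)) set.seed(seed)
  mosaic <- matrix(0, n * np, n * np)
  background <- matrix(0, n * np, n * np)
  for (iv in seq_len(np)) {
    for (iu in seq_len(np)) {
      rows <- seq(iu, by = np, length.out = n)
      cols <- seq(iv, by = np, length.out = n)
      mosaic[rows, cols] <- vig[iu, iv] *
        (L[, , iu, iv] + cfg$background_level)
      background[rows, cols] <- vig[iu, iv] * cfg$background_level
    }
  }
  if (cfg$noise_sd > 0) {
    mosaic <- mosaic + rnorm(length(mosaic), sd = cfg$noise_sd)
  }
  list(
    mosaic = mosaic, background = background,
    lf_truth = light_field(L, opt, angmask), scene = scene
  )
}

#' Straight-rod phantom scene at a fixed depth
#'
#' @param cfg A [render_config()].
#' @param depth_um Axial offset of the rod.
#' @param length_um,radius_um Rod dimensions (defaults span ~60% of the
#'   field of view).
#' @return A [render_worm_scene()] scene.
#' @export
rod_scene <- function(cfg, depth_um = 0, length_um = NULL, radius_um = NULL) {
  pitch_um <- sample_pitch_um(cfg$optics)
  if (is.null(length_um)) length_um <- 0.6 * cfg$n_lenses * pitch_um
  if (is.null(radius_um)) radius_um <- 1.2 * pitch_um
  sk <- cbind(
    x_um = seq(-length_um / 2, length_um / 2, length.out = 27),
    y_um = 0, z_um = depth_um
  )
  render_worm_scene(sk, cfg, radius_um = radius_um, taper = FALSE)
}

#' Synthetic depth-calibration series
#'
#' A static rod phantom rendered at each listed axial offset, emulating a
#' paralysed specimen translated through known focus positions.
#'
#' @param cfg A [render_config()].
#' @param depths_um Vector of known depth offsets in micrometres.
#' @param seed Integer seed for the read noise.
#' @return List of per-depth renders (as [render_light_field()]), with the
#'   known depth attached as `$depth_um`.
#' @export
calibration_series <- function(cfg, depths_um = seq(-1000, 1000, length.out = 21),
                               seed = 1) {
  stopifnot(inherits(cfg, "render_config"))
  lapply(seq_along(depths_um), function(i) {
    r <- render_light_field(
      rod_scene(cfg, depth_um = depths_um[i]), cfg,
      seed = seed + i
    )
    r$depth_um <- depths_um[i]
    r
  })
}

#' Render a bare microlens-lattice mosaic (flat scene)
#'
#' Vignetted subimage discs on an arbitrary (possibly rotated, non-integer
#' pitch) lattice, for exercising lattice estimation.
#'
#' @param size Mosaic side length in pixels.
#' @param pitch Lattice pitch in pixels.
#' @param orientation Rotation in radians.
#' @param offset 0-based pixel position of one subimage centre.
#' @param level Peak intensity.
#' @return `size x size` numeric matrix.
#' @export
render_lattice_mosaic <- function(size = 494, pitch = 19,
                                  orientation = 0, offset = NULL,
                                  level = 1000) {
  if (is.null(offset)) offset <- c((pitch - 1) / 2, (pitch - 1) / 2)
  px <- matrix(seq_len(size) - 1, size, size)
  py <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  co <- cos(-orientation)
  si <- sin(-orientation)
  rx <- co * (px - offset[1]) - si * (py - offset[2])
  ry <- si * (px - offset[1]) + co * (py - offset[2])
  lx <- rx - pitch * round(rx / pitch)
  ly <- ry - pitch * round(ry / pitch)
  r2 <- (lx^2 + ly^2) / (0.475 * pitch)^2
  level * pmax(1 - r2, 0)
}
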