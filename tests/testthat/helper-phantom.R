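# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Optics used by the worm-scene fixtures: coarser lenses at lower
# magnification so a several-hundred-micrometre worm fits the mosaic.
worm_optics <- function() {
  lf_optics(pitch_px = 9, mla_focal_um = 1500, magnification = 5)
}

# A 3D sinusoidal worm spanning ~+/-150 um in depth, rendered and pushed
# through rectification, segmentation and depth estimation once.
worm_scene_fixture <- function() {
  fixture("worm_scene", function() {
    opt <- worm_optics()
    cfg <- render_config(opt, n_lenses = 96)
    s <- seq(0, 1, length.out = 27)
    sk <- cbind(
      x_um = (s - 0.5) * 700,
      y_um = 120 * sin(2 * pi * s / 0.9),
      z_um = 150 * sin(2 * pi * s / 1.3 + 0.4)
    )
    scene <- render_worm_scene(sk, cfg, radius_um = 35)
    render <- render_light_field(scene, cfg)
    lf <- resample_to_4d(
      correct_vignetting(render$mosaic, render$background),
      lf_lattice(9, 0, c(4, 4)), opt
    )
    mask <- segment_worm(pinhole_view(lf, 0, 0), min_area = 100)
    sweep <- depth_sweep(opt, -250, 250, 128)
    dm <- estimate_depth(lf, sweep, footprint = mask$mask)
    list(
      optics = opt, cfg = cfg, skeleton_true = sk, scene = scene,
      render = render, lf = lf, mask = mask, sweep = sweep, depth = dm
    )
  })
}

# Short rendered sequence of an undulating worm (for arc-length stability
# and temporal filtering): 4 frames, body length conserved by construction.
worm_sequence_fixture <- function() {
  fixture("worm_sequence", function() {
    opt <- worm_optics()
    cfg <- render_config(opt, n_lenses = 96)
    loc <- generate_locomotion(
      locomotion_params(
        body_length_um = 600, amplitude_rad = 0.5, speed_um_s = 0,
        angle_noise_rad = 0, seed = 11
      ),
      n_frames = 4, dt_s = 0.1
    )
    sweep <- depth_sweep(opt, -250, 250, 128)
    lat <- lf_lattice(9, 0, c(4, 4))
    frames <- lapply(split(loc$skeletons, loc$skeletons$frame), function(skf) {
      scene <- render_worm_scene(
        skf[, c("x_um", "y_um", "z_um")], cfg,
        radius_um = 30
      )
      render <- render_light_field(scene, cfg)
      lf <- resample_to_4d(
        correct_vignetting(render$mosaic, render$background), lat, opt
      )
      mask <- segment_worm(pinhole_view(lf, 0, 0), min_area = 100)
      dm <- estimate_depth(lf, sweep, footprint = mask$mask)
      list(scene = scene, mask = mask, depth = dm)
    })
    list(optics = opt, cfg = cfg, loc = loc, sweep = sweep, frames = frames)
  })
}

# Full noiseless / noisy rod calibration series over +/-1 mm.
calibration_fixture <- function(noisy = FALSE) {
  key <- if (noisy) "calib_noisy" else "calib_clean"
  fixture(key, function() {
    opt <- lf_optics()
    cfg <- render_config(opt,
      n_lenses = 26,
      noise_sd = if (noisy) 10 else 0
    )
    depths <- seq(-1000, 1000, length.out = 21)
    sweep <- depth_sweep(opt, -1000, 1000, 256)
    lat <- lf_lattice(19, 0, c(9, 9))
    series <- calibration_series(cfg, depths, seed = 42)
    est <- vapply(series, function(r) {
      lf <- resample_to_4d(
        correct_vignetting(r$mosaic, r$background), lat, opt
      )
      dm <- estimate_depth(lf, sweep, footprint = r$scene$footprint)
      mean(dm$depth_um[r$scene$footprint], na.rm = TRUE)
    }, numeric(1))
    list(
      depths = depths, estimated = est,
      calibration = calibrate_depth_scale(est, depths)
    )
  })
}

# Independent reference implementation of the sweep statistics: direct
# evaluation of the sheared light field (object-frame, Catmull-Rom in R)
# and of the response definitions, for oracle-equivalence tests.
reference_sweep_stats <- function(lf, alphas) {
  d <- dim(lf$radiance)
  uc <- seq_len(d[3]) - 1 - (d[3] - 1) / 2
  vc <- seq_len(d[4]) - 1 - (d[4] - 1) / 2
  cr <- function(f) {
    c(
      0.5 * (-f^3 + 2 * f^2 - f), 0.5 * (3 * f^3 - 5 * f^2 + 2),
      0.5 * (-3 * f^3 + 4 * f^2 + f), 0.5 * (f^3 - f^2)
    )
  }
  fetch <- function(img, xi, yi) {
    nx <- nrow(img)
    ny <- ncol(img)
    if (xi < 0 || yi < 0 || xi > nx - 1 || yi > ny - 1) {
      return(NA_real_)
    }
    x0 <- min(floor(xi), nx - 2)
    y0 <- min(floor(yi), ny - 2)
    wx <- cr(xi - x0)
    wy <- cr(yi - y0)
    acc <- 0
    for (j in 1:4) {
      yj <- min(max(y0 - 1 + (j - 1), 0), ny - 1)
      row <- 0
      for (i in 1:4) {
        xi_ <- min(max(x0 - 1 + (i - 1), 0), nx - 1)
        row <- row + wx[i] * img[xi_ + 1, yj + 1]
      }
      acc <- acc + wy[j] * row
    }
    acc
  }
  out <- list(
    sum = array(0, c(d[1], d[2], length(alphas))),
    sumsq = array(0, c(d[1], d[2], length(alphas))),
    count = array(0L, c(d[1], d[2], length(alphas)))
  )
  for (k in seq_along(alphas)) {
    sh <- 1 - 1 / alphas[k]
    for (iv in seq_len(d[4])) {
      for (iu in seq_len(d[3])) {
        if (!lf$angular_mask[iu, iv]) next
        img <- lf$radiance[, , iu, iv]
        for (y in seq_len(d[2])) {
          for (x in seq_len(d[1])) {
            val <- fetch(img, (x - 1) + uc[iu] * sh, (y - 1) + vc[iv] * sh)
            if (is.finite(val)) {
              out$sum[x, y, k] <- out$sum[x, y, k] + val
              out$sumsq[x, y, k] <- out$sumsq[x, y, k] + val^2
              out$count[x, y, k] <- out$count[x, y, k] + 1L
            }
          }
        }
      }
    }
  }
  out
}

# Exhaustive minimiser of the fusion energy for tiny instances.
exhaustive_mrf_energy <- function(lab_assign, fp, wd, wc, ld, lc, lambda, tau) {
  nr <- nrow(fp)
  nc <- ncol(fp)
  lab <- matrix(NA_integer_, nr, nc)
  lab[which(fp)] <- lab_assign
  e <- 0
  for (p in which(fp)) {
    e <- e + wd[p] * abs(lab[p] - ld[p]) + wc[p] * abs(lab[p] - lc[p])
  }
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!fp[i, j]) next
      if (i < nr && fp[i + 1, j]) {
        e <- e + lambda * min(abs(lab[i, j] - lab[i + 1, j]), tau)
      }
      if (j < nc && fp[i, j + 1]) {
        e <- e + lambda * min(abs(lab[i, j] - lab[i, j + 1]), tau)
      }
    }
  }
  e
}

# Build a cue_depth object directly (for fusion tests).
make_cue <- function(label, confidence, sweep,
                     reliable = matrix(TRUE, nrow(label), ncol(label)),
                     cue = "defocus") {
  structure(
    list(
      label = label,
      alpha_star = matrix(sweep$alphas[label], nrow(label), ncol(label)),
      depth_um = matrix(sweep$depths_um[label], nrow(label), ncol(label)),
      confidence = confidence, reliable = reliable,
      cue = cue, sweep = sweep
    ),
    class = "cue_depth"
  )
}
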