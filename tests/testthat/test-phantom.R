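test_that("the generator is deterministic given a seed", {
  p <- locomotion_params(seed = 31)
  a <- generate_locomotion(p, n_frames = 20)
  b <- generate_locomotion(p, n_frames = 20)
  expect_identical(a$skeletons, b$skeletons)
  expect_identical(a$angles, b$angles)
  cfg <- render_config(lf_optics(), n_lenses = 16)
  r1 <- render_light_field(rod_scene(cfg, 200), cfg, seed = 5)
  r2 <- render_light_field(rod_scene(cfg, 200), cfg, seed = 5)
  expect_identical(r1$mosaic, r2$mosaic)
})

test_that("degenerate locomotion parameters give degenerate motion", {
  # zero amplitude: a straight swimming rod, all angles zero
  loc0 <- generate_locomotion(
    locomotion_params(amplitude_rad = 0, angle_noise_rad = 0, seed = 1),
    n_frames = 5
  )
  expect_lt(max(abs(loc0$angles$theta)), 1e-12)
  expect_lt(max(abs(loc0$angles$phi)), 1e-12)
  # infinite roll ratio: planar motion, true polar angles all zero
  locp <- generate_locomotion(
    locomotion_params(roll_ratio = Inf, angle_noise_rad = 0, seed = 1),
    n_frames = 10
  )
  expect_lt(max(abs(locp$angles$phi)), 1e-12)
  expect_lt(max(abs(locp$skeletons$z_um)), 1e-9)
})

test_that("generated locomotion conserves body length per frame", {
  loc <- generate_locomotion(locomotion_params(seed = 17), n_frames = 25)
  for (f in unique(loc$skeletons$frame)) {
    skf <- loc$skeletons[loc$skeletons$frame == f, ]
    len <- sum(sqrt(diff(skf$x_um)^2 + diff(skf$y_um)^2 + diff(skf$z_um)^2))
    expect_equal(len, 1000, tolerance = 1e-6)
  }
})

test_that("the centroid advances at the configured speed", {
  loc <- generate_locomotion(
    locomotion_params(speed_um_s = 80, angle_noise_rad = 0, seed = 2),
    n_frames = 40, dt_s = 0.05
  )
  tr <- track_from_skeletons(loc$skeletons)
  fit <- lm(x_um ~ time_s, data = tr)
  expect_equal(unname(coef(fit)[2]), 80, tolerance = 2)
})

test_that("a straight rod scene has the analytic footprint and flat depth", {
  # fine grid relative to the radius so pixel quantisation stays small
  cfg <- render_config(
    lf_optics(pitch_px = 9, mla_focal_um = 1500, magnification = 10),
    n_lenses = 96
  )
  pitch <- sample_pitch_um(cfg$optics) # 5.85 um
  len <- 400
  rad <- 40
  sk <- cbind(x_um = c(-len / 2, len / 2), y_um = 0, z_um = 0)
  sc <- render_worm_scene(sk, cfg,
    radius_um = rad, taper = FALSE,
    texture_amp = 0, blur_sigma = 0
  )
  expect_true(all(sc$depth_um[sc$footprint] == 0))
  area_px <- sum(sc$footprint) * pitch^2
  area_true <- 2 * rad * len + pi * rad^2 # stadium: rectangle + end caps
  expect_lt(abs(area_px - area_true) / area_true, 0.05)
})

test_that("a tilted rod's depth truth is the analytic ramp", {
  cfg <- render_config(lf_optics(), n_lenses = 26)
  pitch <- sample_pitch_um(cfg$optics)
  sk <- cbind(
    x_um = seq(-7, 7, length.out = 20) * pitch, y_um = 0,
    z_um = seq(-200, 200, length.out = 20)
  )
  sc <- render_worm_scene(sk, cfg,
    radius_um = 1.4 * pitch, taper = FALSE,
    texture_amp = 0, blur_sigma = 0
  )
  on <- which(sc$footprint, arr.ind = TRUE)
  x_um <- (on[, 1] - 1 - 12.5) * pitch
  slope <- 400 / (14 * pitch)
  pred <- pmin(pmax(x_um * slope, -200), 200)
  expect_lt(max(abs(sc$depth_um[on] - pred)), 2 * slope * pitch)
})

test_that("a scene at the native plane renders with zero disparity", {
  cfg <- render_config(lf_optics(),
    n_lenses = 20, vignette_strength = 0,
    background_level = 0
  )
  r <- render_light_field(rod_scene(cfg, depth_um = 0), cfg)
  v0 <- pinhole_view(r$lf_truth, 0, 0)
  for (u in c(-7, 3)) {
    expect_equal(pinhole_view(r$lf_truth, u, 0), v0, tolerance = 1e-12)
  }
})

test_that("refocusing at the rendering depth collapses angular variance", {
  opt <- lf_optics()
  cfg <- render_config(opt, n_lenses = 26)
  dz <- 450
  r <- render_light_field(rod_scene(cfg, depth_um = dz), cfg)
  a_star <- depth_to_shear(dz, opt)
  sig_at <- function(alpha) {
    st <- wormlf:::lf_sweep_stats(r$lf_truth, alpha, object_frame = TRUE)
    mu <- st$sum[, , 1] / pmax(st$count[, , 1], 1)
    sig2 <- st$sumsq[, , 1] / pmax(st$count[, , 1], 1) - mu^2
    mean(sqrt(pmax(sig2, 0))[r$scene$footprint])
  }
  s_true <- sig_at(a_star)
  s_off <- sig_at(depth_to_shear(dz - 300, opt))
  s_native <- sig_at(1)
  # collapse by an order of magnitude relative to misfocused shears
  expect_lt(s_true, 0.1 * s_off)
  expect_lt(s_true, 0.1 * s_native)
})

test_that("the renderer is the adjoint of refocus for uniform-depth scenes", {
  opt <- lf_optics()
  cfg <- render_config(opt,
    n_lenses = 26, vignette_strength = 0,
    background_level = 0
  )
  dz <- 350
  r <- render_light_field(rod_scene(cfg, depth_um = dz), cfg)
  # integrate the sheared field in the native object frame (undoing the
  # alpha rescaling of the photograph) and compare with the scene
  a <- depth_to_shear(dz, opt)
  st <- wormlf:::lf_sweep_stats(r$lf_truth, a, object_frame = TRUE)
  refoc <- st$sum[, , 1] / pmax(st$count[, , 1], 1)
  target <- r$scene$intensity * cfg$peak_signal
  keep <- r$scene$footprint
  rms <- sqrt(mean((refoc[keep] - target[keep])^2))
  expect_lt(rms, 0.02 * diff(range(target)))
})

test_that("calibration series are reproducible and monotone in true depth", {
  fx <- calibration_fixture(noisy = FALSE)
  expect_true(all(diff(fx$estimated) > 0))
  cfg <- render_config(lf_optics(), n_lenses = 16)
  s1 <- calibration_series(cfg, c(-300, 0, 300), seed = 4)
  s2 <- calibration_series(cfg, c(-300, 0, 300), seed = 4)
  expect_identical(s1[[2]]$mosaic, s2[[2]]$mosaic)
  expect_equal(s1[[1]]$depth_um, -300)
})

test_that("unreachable scene depths are rejected by the renderer", {
  opt <- lf_optics()
  cfg <- render_config(opt, n_lenses = 16)
  expect_error(
    rod_scene(cfg, depth_um = depth_limit(opt) + 100) |>
      render_light_field(cfg),
    "unreachable"
  )
})
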