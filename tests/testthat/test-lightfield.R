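# Small helper: a smooth synthetic light field (no depth structure) for
# interpolation-tolerance properties.
centred_coords <- wormlf:::centred_coords

smooth_light_field <- function(n = 21, nu = 5, optics = lf_optics(pitch_px = nu)) {
  xc <- centred_coords(n)
  img <- outer(xc, xc, function(x, y) {
    2 + sin(2 * pi * x / 11) * cos(2 * pi * y / 13) + 0.3 * cos(2 * pi * x / 7)
  })
  rad <- array(rep(img, nu * nu), dim = c(n, n, nu, nu))
  light_field(rad, optics)
}

test_that("vignetting correction divides by the background and flags dark pixels", {
  set.seed(1)
  raw <- matrix(runif(30 * 30, 10, 100), 30, 30)
  expect_equal(unclass(correct_vignetting(raw, raw))[, ],
    matrix(1, 30, 30),
    ignore_attr = TRUE
  )
  expect_equal(correct_vignetting(2 * raw, raw)[1:30, ],
    matrix(2, 30, 30),
    ignore_attr = TRUE
  )
  # radial cos^4-type vignette divided out leaves a flat field
  xc <- centred_coords(30)
  vig <- outer(xc, xc, function(x, y) cos(sqrt(x^2 + y^2) / 40)^4)
  flat <- matrix(500, 30, 30)
  corr <- correct_vignetting(flat * vig, 500 * vig)
  expect_lt(max(abs(corr - 1)), 1e-6)
  expect_error(correct_vignetting(raw, raw[1:10, 1:10]), "same shape")
  expect_error(correct_vignetting(raw, matrix(0, 30, 30)), "all zero")
  # flagged pixels where background below the floor
  bg <- matrix(1000, 30, 30)
  bg[3, 7] <- 1e-9
  out <- correct_vignetting(raw, bg)
  expect_true(attr(out, "flagged")[3, 7])
  expect_equal(out[3, 7], 0)
})

test_that("pinhole views select angular samples and reject masked ones", {
  lf <- smooth_light_field()
  v <- pinhole_view(lf, 0, 0)
  expect_equal(v, lf$radiance[, , 3, 3])
  # corners of the square subimage lie outside the circular aperture
  expect_error(pinhole_view(lf, 2, 2), "aperture")
  expect_error(pinhole_view(lf, 9, 0), "aperture")
})

test_that("refocus at alpha = 1 is the identity on valid views", {
  lf <- smooth_light_field()
  out <- refocus(lf, 1)
  for (iu in 1:5) {
    for (iv in 1:5) {
      if (lf$angular_mask[iu, iv]) {
        expect_identical(out$radiance[, , iu, iv], lf$radiance[, , iu, iv])
      }
    }
  }
  expect_error(refocus(lf, 0), "positive")
  expect_error(refocus(lf, -2), "positive")
})

test_that("flat light fields are fixed points of refocus and integration", {
  opt <- lf_optics(pitch_px = 5)
  rad <- array(3.7, dim = c(15, 15, 5, 5))
  lf <- light_field(rad, opt)
  expect_equal(integrate_views(lf)[, ], matrix(3.7, 15, 15),
    ignore_attr = TRUE
  )
  ref <- refocus(lf, 1.4)
  inner <- 5:11
  expect_equal(ref$radiance[inner, inner, 3, 3],
    matrix(3.7, 7, 7),
    tolerance = 1e-12
  )
  expect_equal(integrate_views(ref)[inner, inner], matrix(3.7, 7, 7),
    tolerance = 1e-12
  )
})

test_that("refocus acts as a group on interior pixels of smooth fields", {
  lf <- smooth_light_field()
  a1 <- 1.15
  a2 <- 1.1
  once <- refocus(lf, a1 * a2)
  twice <- refocus(refocus(lf, a1), a2)
  inner <- 7:15
  i1 <- integrate_views(once)[inner, inner]
  i2 <- integrate_views(twice)[inner, inner]
  rms <- sqrt(mean((i1 - i2)^2))
  expect_lt(rms, 0.01 * diff(range(lf$radiance)))
})

test_that("refocus conserves interior radiance within 1%", {
  lf <- smooth_light_field()
  ref <- refocus(lf, 1.2)
  inner <- 6:16
  s0 <- sum(lf$radiance[inner, inner, 3, 3])
  s1 <- sum(ref$radiance[inner, inner, 3, 3], na.rm = TRUE)
  expect_lt(abs(s1 - s0) / s0, 0.01)
})

test_that("integration renormalises by valid sample counts", {
  opt <- lf_optics(pitch_px = 3, aperture_radius_frac = 1)
  rad <- array(0, dim = c(4, 4, 3, 3))
  rad[, , 2, 2] <- 5 # only the central view carries light
  rad[1, 1, 1, 2] <- NA # one invalid sample elsewhere
  lf <- light_field(rad, opt)
  out <- integrate_views(lf)
  nval <- attr(out, "n_valid")
  expect_equal(nval[2, 2], sum(lf$angular_mask))
  expect_equal(nval[1, 1], sum(lf$angular_mask) - 1)
  expect_equal(out[2, 2], 5 / sum(lf$angular_mask))
})

test_that("focal stacks order slices by depth and focus at the source plane", {
  opt <- lf_optics()
  cfg <- render_config(opt, n_lenses = 20)
  scene <- rod_scene(cfg, depth_um = 400, length_um = 60, radius_um = 15)
  r <- render_light_field(scene, cfg)
  sweep <- depth_sweep(opt, -800, 800, 9)
  st <- focal_stack(r$lf_truth, sweep)
  expect_equal(dim(st), c(20, 20, 9))
  expect_equal(attr(st, "depths_um"), sweep$depths_um)
  # sharpest slice (peak intensity) nearest the rendered depth
  peak <- apply(st, 3, max)
  expect_equal(
    sweep$depths_um[which.max(peak)],
    sweep$depths_um[which.min(abs(sweep$depths_um - 400))]
  )
  # flat field: all slices identical in the interior
  flat <- light_field(array(2, dim = c(15, 15, 5, 5)), lf_optics(pitch_px = 5))
  stf <- focal_stack(flat, depth_sweep(lf_optics(pitch_px = 5), -100, 100, 3))
  expect_lt(max(abs(stf[6:10, 6:10, 1] - stf[6:10, 6:10, 3])), 1e-9)
})

test_that("parallax between pinhole views matches the shear model", {
  opt <- lf_optics()
  cfg <- render_config(opt,
    n_lenses = 26, vignette_strength = 0,
    background_level = 0
  )
  dz <- 600
  scene <- rod_scene(cfg, depth_um = dz, length_um = 40, radius_um = 14)
  r <- render_light_field(scene, cfg)
  sh <- 1 - 1 / depth_to_shear(dz, opt)
  centroid_x <- function(img) {
    w <- img / sum(img)
    sum(w * row(img))
  }
  for (u in c(-6, 0, 6)) {
    expect_equal(
      centroid_x(pinhole_view(r$lf_truth, u, 0)) -
        centroid_x(pinhole_view(r$lf_truth, 0, 0)),
      sh * u,
      tolerance = 0.05 * max(1, abs(sh * u))
    )
  }
  # zero parallax at the native plane
  scene0 <- rod_scene(cfg, depth_um = 0, length_um = 40, radius_um = 14)
  r0 <- render_light_field(scene0, cfg)
  expect_equal(
    centroid_x(pinhole_view(r0$lf_truth, 6, 0)),
    centroid_x(pinhole_view(r0$lf_truth, 0, 0)),
    tolerance = 1e-6
  )
})
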