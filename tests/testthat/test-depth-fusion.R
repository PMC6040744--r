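test_that("consensus cues pass through fusion unchanged", {
  opt <- lf_optics()
  sw <- depth_sweep(opt, -100, 100, 5)
  fp <- matrix(TRUE, 3, 4)
  # arbitrary agreeing labels: exact pass-through without smoothing
  set.seed(8)
  lab <- matrix(sample(1:5, 12, TRUE), 3, 4)
  dd <- make_cue(lab, matrix(2, 3, 4), sw)
  dc <- make_cue(lab, matrix(7, 3, 4), sw, cue = "correspondence")
  dm0 <- combine_depth(dd, dc, fp, lambda = 0)
  expect_equal(dm0$label, lab, ignore_attr = TRUE)
  # smoothness-compatible consensus (constant field): invariant to lambda
  labc <- matrix(3L, 3, 4)
  ddc <- make_cue(labc, matrix(2, 3, 4), sw)
  dcc <- make_cue(labc, matrix(7, 3, 4), sw, cue = "correspondence")
  for (lam in c(0.5, 5)) {
    dmc <- combine_depth(ddc, dcc, fp, lambda = lam)
    expect_equal(dmc$label, labc, ignore_attr = TRUE)
  }
  # a unit-step ramp survives the default smoothness weight
  labr <- matrix(rep(1:4, each = 3), 3, 4)
  ddr <- make_cue(labr, matrix(2, 3, 4), sw)
  dcr <- make_cue(labr, matrix(7, 3, 4), sw, cue = "correspondence")
  dmr <- combine_depth(ddr, dcr, fp, lambda = 0.5)
  expect_equal(dmr$label, labr, ignore_attr = TRUE)
})

test_that("degenerate weights reduce fusion to a single cue", {
  opt <- lf_optics()
  sw <- depth_sweep(opt, -100, 100, 7)
  set.seed(2)
  ld <- matrix(sample(1:7, 10, TRUE), 2, 5)
  lc <- matrix(sample(1:7, 10, TRUE), 2, 5)
  dd <- make_cue(ld, matrix(10, 2, 5), sw)
  dc <- make_cue(lc, matrix(1, 2, 5), sw,
    reliable = matrix(FALSE, 2, 5), cue = "correspondence"
  )
  dm <- combine_depth(dd, dc, matrix(TRUE, 2, 5), lambda = 0)
  expect_equal(dm$label, ld, ignore_attr = TRUE)
})

test_that("chain instances match exhaustive minimisation (1x5 strip with outlier)", {
  opt <- lf_optics()
  sw <- depth_sweep(opt, -100, 100, 3)
  ld <- matrix(c(1, 1, 3, 1, 1), 1, 5) # one outlier pixel
  lc <- matrix(1, 1, 5)
  wd <- matrix(c(5, 5, 0.2, 5, 5), 1, 5)
  wc <- matrix(1, 1, 5)
  dd <- make_cue(ld, wd, sw)
  dc <- make_cue(lc, wc, sw, cue = "correspondence")
  fp <- matrix(TRUE, 1, 5)
  dm <- combine_depth(dd, dc, fp, lambda = 0.5, tau = 10)
  wdn <- wd / (wd + wc)
  wcn <- wc / (wd + wc)
  combos <- as.matrix(expand.grid(rep(list(1:3), 5)))
  energies <- apply(combos, 1, exhaustive_mrf_energy,
    fp = fp, wd = wdn, wc = wcn, ld = ld, lc = lc, lambda = 0.5, tau = 10
  )
  expect_equal(
    exhaustive_mrf_energy(dm$label[fp], fp, wdn, wcn, ld, lc, 0.5, 10),
    min(energies)
  )
})

test_that("fusion energy matches exhaustive minimisation on random small grids", {
  opt <- lf_optics()
  set.seed(42)
  for (trial in 1:25) {
    nr <- sample(1:3, 1)
    nc <- sample(1:3, 1)
    if (nr * nc > 6) nc <- max(1, 6 %/% nr)
    K <- sample(2:4, 1)
    sw <- depth_sweep(opt, -100, 100, K)
    fp <- matrix(runif(nr * nc) > 0.15, nr, nc)
    if (!any(fp)) fp[1, 1] <- TRUE
    ld <- matrix(sample(K, nr * nc, TRUE), nr, nc)
    lc <- matrix(sample(K, nr * nc, TRUE), nr, nc)
    wd <- matrix(runif(nr * nc, 1, 5), nr, nc)
    wc <- matrix(runif(nr * nc, 1, 5), nr, nc)
    lam <- runif(1, 0, 1)
    tau <- sample(1:3, 1)
    dd <- make_cue(ld, wd, sw)
    dc <- make_cue(lc, wc, sw, cue = "correspondence")
    dm <- combine_depth(dd, dc, fp, lambda = lam, tau = tau)
    wdn <- wd / (wd + wc)
    wcn <- wc / (wd + wc)
    combos <- as.matrix(expand.grid(rep(list(1:K), sum(fp))))
    energies <- apply(combos, 1, exhaustive_mrf_energy,
      fp = fp, wd = wdn, wc = wcn, ld = ld, lc = lc, lambda = lam, tau = tau
    )
    expect_equal(
      exhaustive_mrf_energy(dm$label[which(fp)], fp, wdn, wcn, ld, lc, lam, tau),
      min(energies),
      tolerance = 1e-9
    )
  }
})

test_that("scanline solver agrees with the exact solver on narrow instances", {
  opt <- lf_optics()
  sw <- depth_sweep(opt, -100, 100, 4)
  set.seed(9)
  ld <- matrix(sample(1:4, 9, TRUE), 3, 3)
  lc <- matrix(sample(1:4, 9, TRUE), 3, 3)
  wd <- matrix(runif(9, 1, 3), 3, 3)
  wc <- matrix(runif(9, 1, 3), 3, 3)
  dd <- make_cue(ld, wd, sw)
  dc <- make_cue(lc, wc, sw, cue = "correspondence")
  fp <- matrix(TRUE, 3, 3)
  d_exact <- combine_depth(dd, dc, fp, solver = "exact")
  d_scan <- combine_depth(dd, dc, fp, solver = "scanline")
  wdn <- wd / (wd + wc)
  wcn <- wc / (wd + wc)
  e <- function(d) {
    exhaustive_mrf_energy(d$label[which(fp)], fp, wdn, wcn, ld, lc, 0.5, 10)
  }
  expect_lte(e(d_scan), e(d_exact) + 1e-9)
})

test_that("fusion rejects empty footprints and flags unreliable flat input", {
  opt <- lf_optics()
  sw <- depth_sweep(opt, -100, 100, 3)
  dd <- make_cue(matrix(1, 2, 2), matrix(1, 2, 2), sw)
  dc <- make_cue(matrix(1, 2, 2), matrix(1, 2, 2), sw, cue = "correspondence")
  expect_error(
    combine_depth(dd, dc, matrix(FALSE, 2, 2)),
    "empty footprint"
  )
  # flat-field light field: estimate_depth flags everything unreliable
  lf <- light_field(
    array(1, dim = c(9, 9, 3, 3)),
    lf_optics(pitch_px = 3, aperture_radius_frac = 1)
  )
  dm <- estimate_depth(lf, depth_sweep(lf$optics, -50, 50, 5), window = 3)
  expect_false(any(dm$reliable))
})

test_that("depth-scale calibration matches closed-form least squares", {
  known <- seq(-500, 500, by = 100)
  cal <- calibrate_depth_scale(known, known)
  expect_equal(cal$gradient, 1)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$rmse_um, 0, tolerance = 1e-10)
  scaled <- calibrate_depth_scale(0.883 * known, known)
  expect_equal(scaled$gradient, 0.883)
  expect_equal(scaled$rmse_um, 0, tolerance = 1e-10)
  hand <- calibrate_depth_scale(c(-95, 5, 105), c(-100, 0, 100))
  expect_equal(hand$gradient, 1)
  expect_equal(hand$intercept_um, 5)
  expect_equal(hand$rmse_um, 0, tolerance = 1e-10)
  expect_error(calibrate_depth_scale(1:2, 1:2), "at least 3")
  expect_error(calibrate_depth_scale(1:3, c(2, 2, 2)), "distinct")
  # broom-style accessors
  td <- tidy(scaled)
  expect_equal(td$estimate[td$term == "gradient"], 0.883)
  gl <- glance(hand)
  expect_equal(gl$r_squared, 1)
  # correction divides by the gradient
  lf <- worm_scene_fixture()
  dmg <- estimate_depth(
    lf$lf, lf$sweep,
    footprint = lf$mask$mask, gradient = 2
  )
  dm1 <- estimate_depth(lf$lf, lf$sweep, footprint = lf$mask$mask)
  expect_equal(dmg$depth_um, dm1$depth_um / 2)
})
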