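straight_track <- function(n = 21, speed = 50, dt = 0.05) {
  tibble::tibble(
    frame = seq_len(n), time_s = (seq_len(n) - 1) * dt,
    x_um = speed * (seq_len(n) - 1) * dt, y_um = 0, z_um = 0
  )
}

circle_track <- function(n = 81, R = 200, omega = 1, dt = 0.05) {
  t <- (seq_len(n) - 1) * dt
  tibble::tibble(
    frame = seq_len(n), time_s = t,
    x_um = R * cos(omega * t), y_um = R * sin(omega * t), z_um = 0
  )
}

test_that("centroid speed matches forward differences", {
  tr <- straight_track(speed = 50, dt = 0.05)
  cs <- centroid_speed(tr)
  expect_equal(nrow(cs), nrow(tr) - 1)
  expect_true(all(abs(cs$speed_um_s - 50) < 1e-9))
  stat <- straight_track(speed = 0)
  expect_true(all(centroid_speed(stat)$speed_um_s == 0))
  # circular motion: speed is chord length per frame interval
  R <- 200
  omega <- 1
  dt <- 0.05
  cc <- centroid_speed(circle_track(R = R, omega = omega, dt = dt))
  expect_equal(cc$speed_um_s,
    rep(2 * R * sin(omega * dt / 2) / dt, nrow(cc)),
    tolerance = 1e-9
  )
  dup <- straight_track()
  dup$time_s[3] <- dup$time_s[2]
  expect_error(centroid_speed(dup), "strictly increasing")
})

test_that("non-planar deviation is zero for planar and collinear postures", {
  s <- seq(0, 1, length.out = 26)
  planar <- tibble::tibble(
    x_um = s * 500, y_um = 100 * sin(2 * pi * s), z_um = 3
  )
  expect_equal(non_planar_deviation(planar), 0, tolerance = 1e-9)
  collinear <- tibble::tibble(x_um = s * 500, y_um = 2 * s * 500, z_um = 0)
  expect_equal(non_planar_deviation(collinear), 0, tolerance = 1e-9)
  expect_error(
    non_planar_deviation(tibble::tibble(
      x_um = rep(1, 5), y_um = rep(2, 5), z_um = rep(3, 5)
    )),
    "degenerate"
  )
})

test_that("non-planar deviation of a helix matches the explicit eigen-solve", {
  t <- seq(0, 2 * pi, length.out = 26)
  helix <- tibble::tibble(
    x_um = 100 * cos(t), y_um = 100 * sin(t), z_um = 30 * t
  )
  pts <- as.matrix(helix)
  ev <- sort(eigen(stats::cov(pts), symmetric = TRUE)$values,
    decreasing = TRUE
  )
  expect_equal(non_planar_deviation(helix), sqrt(ev[3] / ev[1]),
    tolerance = 1e-12
  )
})

test_that("non-planar deviation is invariant under rigid motion", {
  set.seed(10)
  t <- seq(0, 2 * pi, length.out = 26)
  sk <- cbind(100 * cos(t), 80 * sin(2 * t), 40 * t / (2 * pi))
  npd0 <- non_planar_deviation(
    tibble::tibble(x_um = sk[, 1], y_um = sk[, 2], z_um = sk[, 3])
  )
  th <- 0.6
  ph <- 0.3
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  rot <- sk %*% rz %*% rx
  npd1 <- non_planar_deviation(tibble::tibble(
    x_um = rot[, 1] + 500, y_um = rot[, 2] - 80, z_um = rot[, 3] + 9
  ))
  expect_equal(npd1, npd0, tolerance = 1e-9)
})

test_that("curving rate matches the turning geometry", {
  expect_true(all(
    abs(curving_rate(straight_track())$curving_rate_rad_s) < 1e-6
  ))
  # right-angle turn over dt = 0.05 s
  tr <- tibble::tibble(
    frame = 1:3, time_s = c(0, 0.05, 0.1),
    x_um = c(0, 10, 10), y_um = c(0, 0, 10), z_um = 0
  )
  cr <- curving_rate(tr)
  expect_equal(cr$curving_rate_rad_s, (pi / 2) / 0.05, tolerance = 1e-9)
  # circular motion: exterior angle omega*dt per interval
  omega <- 1.2
  dt <- 0.05
  cc <- curving_rate(circle_track(omega = omega, dt = dt))
  expect_equal(cc$curving_rate_rad_s,
    rep(omega, nrow(cc)),
    tolerance = 1e-6
  )
  still <- straight_track(speed = 0)
  expect_warning(out <- curving_rate(still), "zero")
  expect_equal(nrow(out), 0)
})

test_that("curving rate and speed are invariant under time reversal", {
  tr <- circle_track(n = 41)
  rev_tr <- tr[nrow(tr):1, ]
  rev_tr$time_s <- max(tr$time_s) - rev_tr$time_s
  rev_tr$frame <- seq_len(nrow(rev_tr))
  expect_equal(
    sort(centroid_speed(tr)$speed_um_s),
    sort(centroid_speed(rev_tr)$speed_um_s),
    tolerance = 1e-9
  )
  expect_equal(
    sort(curving_rate(tr)$curving_rate_rad_s),
    sort(curving_rate(rev_tr)$curving_rate_rad_s),
    tolerance = 1e-9
  )
})

test_that("directional autocorrelation has D(0) = 1 and the expected limits", {
  tr <- straight_track(n = 30)
  dd <- directional_autocorrelation(tr, max_lag = 10)
  expect_equal(dd$autocorr, rep(1, 11))
  # alternating +x / -x steps: D(1) = -1
  zig <- tibble::tibble(
    frame = 1:11, time_s = (0:10) * 0.05,
    x_um = rep(c(0, 10), length.out = 11), y_um = 0, z_um = 0
  )
  dz <- directional_autocorrelation(zig, max_lag = 2)
  expect_equal(dz$autocorr[1], 1)
  expect_equal(dz$autocorr[2], -1)
  expect_equal(dz$autocorr[3], 1)
  # bounded and non-increasing for a smoothly turning track
  dc <- directional_autocorrelation(circle_track(n = 100), max_lag = 30)
  expect_true(all(dc$autocorr >= -1 - 1e-12 & dc$autocorr <= 1 + 1e-12))
  expect_true(all(diff(dc$autocorr) <= 1e-9))
  expect_error(directional_autocorrelation(tr, max_lag = 40), "max_lag")
})

test_that("direction decay fits recover generating exponentials", {
  t <- seq(0, 5, by = 0.25)
  d1 <- fit_direction_decay(tibble::tibble(lag_s = t, autocorr = exp(-0.25 * t)))
  expect_equal(d1$A, 1, tolerance = 1e-6)
  expect_equal(d1$b, 0.25, tolerance = 1e-6)
  d2 <- fit_direction_decay(
    tibble::tibble(lag_s = t, autocorr = 0.9 * exp(-0.33 * t))
  )
  expect_equal(d2$A, 0.9, tolerance = 1e-6)
  expect_equal(d2$b, 0.33, tolerance = 1e-6)
  d3 <- fit_direction_decay(tibble::tibble(lag_s = t, autocorr = rep(1, length(t))))
  expect_equal(d3$b, 0, tolerance = 1e-6)
  expect_equal(glance(d2)$b, d2$b)
})

test_that("forward runs are detected from speed and body-axis alignment", {
  dt <- 0.05
  n1 <- 30
  n2 <- 10
  n3 <- 20
  # forward phase, pause, reverse phase; nose leads +x
  xs <- c(
    seq(0, by = 50 * dt, length.out = n1),
    rep(50 * dt * (n1 - 1), n2),
    seq(50 * dt * (n1 - 1), by = -50 * dt, length.out = n3)
  )
  n <- length(xs)
  track <- tibble::tibble(
    frame = seq_len(n), time_s = (seq_len(n) - 1) * dt,
    x_um = xs, y_um = 0, z_um = 0
  )
  skeletons <- dplyr::bind_rows(lapply(seq_len(n), function(f) {
    tibble::tibble(
      frame = f, time_s = (f - 1) * dt, point = 0:25,
      x_um = xs[f] + seq(0, -400, length.out = 26), # nose at +x end
      y_um = 0, z_um = 0
    )
  }))
  runs <- detect_forward_runs(track, skeletons)
  expect_equal(nrow(runs), 1)
  expect_lte(runs$start_frame, 2)
  expect_gte(runs$end_frame, n1 - 1)
  expect_lt(runs$end_frame, n1 + n2) # reverse phase excluded
  # uniformly forward: single interval covering all transitions
  fwd <- detect_forward_runs(
    track[1:n1, ], skeletons[skeletons$frame <= n1, ]
  )
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$start_frame, 1)
  # all-pause: empty
  still_tr <- tibble::tibble(
    frame = 1:20, time_s = (0:19) * dt, x_um = 0, y_um = 0, z_um = 0
  )
  still_sk <- skeletons[skeletons$frame <= 20, ]
  expect_equal(nrow(detect_forward_runs(still_tr, still_sk)), 0)
})

test_that("occupied volumes convert bounding boxes to mm^3", {
  # single skeleton spanning a 300 um cube -> 0.027 mm^3
  sk <- tibble::tibble(
    frame = 1, time_s = 0, point = 0:25,
    x_um = seq(0, 300, length.out = 26),
    y_um = seq(0, 300, length.out = 26),
    z_um = seq(0, 300, length.out = 26)
  )
  v <- occupied_volume(sk)
  expect_equal(v$body_volume_mm3, 0.027)
  # coplanar points occupy zero volume
  flat <- sk
  flat$z_um <- 5
  expect_equal(occupied_volume(flat)$body_volume_mm3, 0)
  # nose exploring a 0.2 x 0.3 x 0.15 mm box -> 0.009 mm^3
  noses <- tibble::tibble(
    frame = 1:8, time_s = (1:8) * 0.05, point = 0,
    x_um = c(0, 200, 0, 200, 0, 200, 0, 200),
    y_um = c(0, 0, 300, 300, 0, 0, 300, 300),
    z_um = c(0, 0, 0, 0, 150, 150, 150, 150)
  )
  expect_equal(occupied_volume(noses)$nose_volume_mm3, 0.009)
})

test_that("strain comparison reproduces the closed-form Welch t-test", {
  a <- tibble::tibble(worm = 1:3, speed = c(1, 2, 3))
  same <- compare_strains(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  b <- tibble::tibble(worm = 1:3, speed = c(11.001, 12, 12.999))
  shifted <- compare_strains(a, b)
  expect_lt(shifted$p_value, 0.001)
  # hand-computed Welch statistic and Welch-Satterthwaite df
  set.seed(20)
  ga <- tibble::tibble(worm = 1:6, speed = rnorm(6, 46.1, 5.7))
  gb <- tibble::tibble(worm = 1:8, speed = rnorm(8, 47.0, 6.7))
  out <- compare_strains(ga, gb)
  va <- var(ga$speed) / 6
  vb <- var(gb$speed) / 8
  t_hand <- (mean(ga$speed) - mean(gb$speed)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 5 + vb^2 / 7)
  expect_equal(out$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$df, df_hand, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * stats::pt(-abs(t_hand), df_hand),
    tolerance = 1e-12
  )
  # SEM computed over worms, not frames
  expect_equal(out$sem_a, sd(ga$speed) / sqrt(6))
})

test_that("per-worm group SEM matches brute-force two-level aggregation", {
  set.seed(30)
  frames <- dplyr::bind_rows(lapply(1:5, function(w) {
    tibble::tibble(worm = w, speed = rnorm(40, mean = 40 + w, sd = 6))
  }))
  per_worm <- dplyr::summarise(dplyr::group_by(frames, worm),
    speed = mean(speed), .groups = "drop"
  )
  cmp <- compare_strains(per_worm, per_worm)
  means <- tapply(frames$speed, frames$worm, mean)
  expect_equal(cmp$mean_a, mean(means), tolerance = 1e-12)
  expect_equal(cmp$sem_a, sd(means) / sqrt(5), tolerance = 1e-12)
})
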