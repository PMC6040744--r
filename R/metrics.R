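# Posture and locomotion metrics computed from skeleton time series:
# centroid speed, non-planar deviation, curving rate, directional
# autocorrelation and its exponential decay, forward-run detection,
# occupied volumes, and per-worm strain comparison.

#' Build a track (centroid time series) from skeletons
#'
#' @param skeletons Tibble with columns `frame`, `time_s`, `point`, `x_um`,
#'   `y_um`, `z_um` (one skeleton per frame, as produced by
#'   [generate_locomotion()] or repeated [extract_midline()]).
#' @return Tibble with one row per frame: `frame`, `time_s`, centroid
#'   `x_um`, `y_um`, `z_um` (mean over skeleton points).
#' @export
track_from_skeletons <- function(skeletons) {
  stopifnot(all(c("frame", "time_s", "x_um", "y_um", "z_um") %in%
    names(skeletons)))
  skeletons %>%
    group_by(.data$frame, .data$time_s) %>%
    summarise(
      x_um = mean(.data$x_um), y_um = mean(.data$y_um),
      z_um = mean(.data$z_um), .groups = "drop"
    ) %>%
    arrange(.data$time_s)
}

# successive displacement vectors of a track; rows = N-1 transitions
track_displacements <- function(track) {
  stopifnot(nrow(track) >= 2)
  if (any(diff(track$time_s) <= 0)) stop("times must be strictly increasing")
  cbind(
    diff(track$x_um), diff(track$y_um), diff(track$z_um)
  )
}

#' Centroid speed series
#'
#' \eqn{CS_i = |r_{i+1} - r_i| / (t_{i+1} - t_i)} from successive centroid
#' positions; length N-1 for N frames.
#'
#' @param track Tibble from [track_from_skeletons()].
#' @return Tibble: `frame`, `time_s`, `speed_um_s`.
#' @export
centroid_speed <- function(track) {
  d <- track_displacements(track)
  dt <- diff(track$time_s)
  tibble::tibble(
    frame = track$frame[-nrow(track)],
    time_s = track$time_s[-nrow(track)],
    speed_um_s = sqrt(rowSums(d^2)) / dt
  )
}

#' Non-planar deviation of a posture
#'
#' \eqn{NPD = R_3 / R_1} where \eqn{R_1 \ge R_2 \ge R_3} are the principal
#' axis lengths (square roots of the covariance eigenvalues) of the best-fit
#' ellipsoid to the skeleton points. 0 for planar or collinear postures,
#' approaching 1 for isotropically 3D ones.
#'
#' @param skeleton Tibble/data frame with `x_um`, `y_um`, `z_um` (>= 4
#'   points, not all identical).
#' @return NPD in \[0, 1\].
#' @export
non_planar_deviation <- function(skeleton) {
  pts <- as.matrix(as.data.frame(skeleton)[, c("x_um", "y_um", "z_um")])
  stopifnot(nrow(pts) >= 4)
  if (all(apply(pts, 2, var) == 0)) stop("degenerate skeleton (single point)")
  ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  sqrt(ev[3] / ev[1])
}

#' Curving rate series
#'
#' Angle between successive centroid displacement vectors per unit time
#' (rad/s). The folded form (absolute dot product, angles in \[0, pi/2\])
#' matches the published metric; `signed_angles = TRUE` uses the full
#' angle in \[0, pi\]. Transitions with zero displacement are skipped.
#'
#' @param track Tibble from [track_from_skeletons()] (>= 3 frames).
#' @param signed_angles Use the unfolded angle.
#' @return Tibble: `frame`, `time_s`, `curving_rate_rad_s`.
#' @export
curving_rate <- function(track, signed_angles = FALSE) {
  stopifnot(nrow(track) >= 3)
  d <- track_displacements(track)
  nrm <- sqrt(rowSums(d^2))
  keep <- which(nrm[-length(nrm)] > 0 & nrm[-1] > 0)
  if (length(keep) == 0) {
    warning("all displacements are zero")
    return(tibble::tibble(
      frame = integer(0), time_s = numeric(0),
      curving_rate_rad_s = numeric(0)
    ))
  }
  dots <- rowSums(d[keep, , drop = FALSE] * d[keep + 1, , drop = FALSE]) /
    (nrm[keep] * nrm[keep + 1])
  if (!signed_angles) dots <- abs(dots)
  ang <- acos(pmin(pmax(dots, -1), 1))
  dt <- track$time_s[keep + 2] - track$time_s[keep + 1]
  tibble::tibble(
    frame = track$frame[keep + 1],
    time_s = track$time_s[keep + 1],
    curving_rate_rad_s = ang / dt
  )
}

#' Directional autocorrelation of a track
#'
#' \eqn{D(n) = (N-n)^{-1} \sum_i v_i \cdot v_{i+n}} over unit centroid
#' displacement direction vectors; \eqn{D(0) = 1}.
#'
#' @param track Tibble from [track_from_skeletons()].
#' @param max_lag Largest lag in frames (< number of direction vectors).
#' @return Tibble: `lag`, `lag_s`, `autocorr`.
#' @export
directional_autocorrelation <- function(track, max_lag) {
  d <- track_displacements(track)
  nrm <- sqrt(rowSums(d^2))
  v <- d / ifelse(nrm > 0, nrm, 1)
  v[nrm == 0, ] <- NA_real_
  n <- nrow(v)
  if (max_lag >= n) stop("max_lag too large for this track")
  dt <- mean(diff(track$time_s))
  ac <- vapply(0:max_lag, function(lag) {
    i <- seq_len(n - lag)
    mean(rowSums(v[i, , drop = FALSE] * v[i + lag, , drop = FALSE]),
      na.rm = TRUE
    )
  }, numeric(1))
  tibble::tibble(lag = 0:max_lag, lag_s = (0:max_lag) * dt, autocorr = ac)
}

#' Exponential decay fit to a directional autocorrelation curve
#'
#' Nonlinear least squares of \eqn{D(t) = A e^{-b t}}; `b` (1/s) is the
#' directional decay constant.
#'
#' @param autocorr Tibble from [directional_autocorrelation()] (or with
#'   columns `lag_s`, `autocorr`; >= 3 lags).
#' @return Object of class `direction_decay` with `A`, `b`, `residual_norm`.
#' @export
fit_direction_decay <- function(autocorr) {
  stopifnot(nrow(autocorr) >= 3)
  t <- autocorr$lag_s
  y <- autocorr$autocorr
  if (sd(y) < 1e-12) {
    # constant curve: zero decay, exact fit
    return(structure(
      list(
        A = mean(y), b = 0, residual_norm = 0,
        data = tibble::tibble(lag_s = t, autocorr = y)
      ),
      class = "direction_decay"
    ))
  }
  b0 <- {
    pos <- y > 0.05
    if (sum(pos) >= 2 && sd(t[pos]) > 0) {
      max(-unname(coef(lm(log(y[pos]) ~ t[pos]))[2]), 1e-6)
    } else {
      1
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-b * t),
      start = list(A = max(y), b = b0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("decay fit did not converge: ", conditionMessage(e))
  )
  cf <- coef(fit)
  structure(
    list(
      A = unname(cf["A"]), b = unname(cf["b"]),
      residual_norm = sqrt(sum(stats::resid(fit)^2)),
      data = tibble::tibble(lag_s = t, autocorr = y)
    ),
    class = "direction_decay"
  )
}

#' @export
print.direction_decay <- function(x, ...) {
  cat(sprintf(
    "<direction_decay> D(t) = %.3f * exp(-%.3f t)\n", x$A, x$b
  ))
  invisible(x)
}

#' @rdname fit_direction_decay
#' @param x A `direction_decay` object.
#' @param ... Unused.
#' @export
glance.direction_decay <- function(x, ...) {
  tibble::tibble(A = x$A, b = x$b, residual_norm = x$residual_norm)
}

#' Detect forward runs in a track
#'
#' Maximal frame intervals in which the centroid speed stays at or above
#' `speed_min_um_s` and the displacement direction has a positive component
#' along the tail-to-nose body axis, sustained for at least
#' `min_duration_s`.
#'
#' @param track Tibble from [track_from_skeletons()].
#' @param skeletons Skeleton tibble (for the tail-to-nose axis per frame).
#' @param speed_min_um_s Speed threshold.
#' @param min_duration_s Minimal sustained duration.
#' @return Tibble of intervals: `start_frame`, `end_frame`, `duration_s`
#'   (empty when no run qualifies).
#' @export
detect_forward_runs <- function(track, skeletons, speed_min_um_s = 10,
                                min_duration_s = 0.5) {
  cs <- centroid_speed(track)
  d <- track_displacements(track)
  axes <- skeletons %>%
    group_by(.data$frame) %>%
    summarise(
      ax = .data$x_um[which.min(.data$point)] -
        .data$x_um[which.max(.data$point)],
      ay = .data$y_um[which.min(.data$point)] -
        .data$y_um[which.max(.data$point)],
      az = .data$z_um[which.min(.data$point)] -
        .data$z_um[which.max(.data$point)],
      .groups = "drop"
    )
  ax <- axes[match(cs$frame, axes$frame), ]
  fwd <- rowSums(d * cbind(ax$ax, ax$ay, ax$az)) > 0
  good <- cs$speed_um_s >= speed_min_um_s & fwd
  good[is.na(good)] <- FALSE
  runs <- rle(good)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  out <- tibble::tibble(
    start_frame = cs$frame[starts[keep]],
    end_frame = cs$frame[ends[keep]] + 1L,
    duration_s = track$time_s[match(cs$frame[ends[keep]], track$frame) + 1] -
      track$time_s[match(cs$frame[starts[keep]], track$frame)]
  )
  out[out$duration_s >= min_duration_s, ]
}

#' Volume explored by the body and the nose
#'
#' Axis-aligned bounding-box volumes (mm^3) of all skeleton points over the
#' sequence (body) and of the nose points only.
#'
#' @param skeletons Skeleton tibble over frames (`point` 0 = nose).
#' @param hull Use 3D convex-hull volumes instead of bounding boxes
#'   (requires \pkg{geometry}; bounding boxes are the published definition).
#' @return Tibble: `body_volume_mm3`, `nose_volume_mm3`.
#' @export
occupied_volume <- function(skeletons, hull = FALSE) {
  stopifnot(nrow(skeletons) >= 1)
  box_vol <- function(df) {
    if (nrow(df) == 0) {
      return(0)
    }
    prod(
      diff(range(df$x_um)), diff(range(df$y_um)), diff(range(df$z_um))
    ) / 1e9
  }
  vol <- if (hull && requireNamespace("geometry", quietly = TRUE)) {
    function(df) {
      pts <- unique(as.matrix(df[, c("x_um", "y_um", "z_um")]))
      if (nrow(pts) < 4) {
        return(0)
      }
      geometry::convhulln(pts, options = "FA")$vol / 1e9
    }
  } else {
    box_vol
  }
  tibble::tibble(
    body_volume_mm3 = vol(skeletons),
    nose_volume_mm3 = vol(skeletons[skeletons$point == 0, ])
  )
}

#' Compare per-worm metric means between two strains
#'
#' Welch two-sample t-test (unequal variances) per metric on per-worm mean
#' values, with group means and standard errors computed over worms (not
#' frames).
#'
#' @param group_a,group_b Tibbles of per-worm means: a `worm` identifier
#'   column plus one numeric column per metric (>= 2 worms each).
#' @return Tibble: `metric`, `mean_a`, `sem_a`, `mean_b`, `sem_b`,
#'   `t_statistic`, `df`, `p_value`. Metrics with zero variance in both
#'   groups get `NA` p-values.
#' @export
compare_strains <- function(group_a, group_b) {
  metrics <- intersect(
    names(group_a)[vapply(group_a, is.numeric, logical(1))],
    names(group_b)[vapply(group_b, is.numeric, logical(1))]
  )
  metrics <- setdiff(metrics, "worm")
  stopifnot(length(metrics) >= 1, nrow(group_a) >= 2, nrow(group_b) >= 2)
  sem <- function(x) sd(x) / sqrt(length(x))
  purrr::map_dfr(metrics, function(m) {
    a <- group_a[[m]]
    b <- group_b[[m]]
    tt <- if (sd(a) == 0 && sd(b) == 0) {
      list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
    } else {
      t.test(a, b, var.equal = FALSE)
    }
    tibble::tibble(
      metric = m,
      mean_a = mean(a), sem_a = sem(a),
      mean_b = mean(b), sem_b = sem(b),
      t_statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
}
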