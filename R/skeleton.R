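#' Two-frame temporal Kalman filter for depth-map sequences
#'
#' Per-pixel scalar Kalman filter with a constant-position state model using
#' only the current and previous frame: the previous frame's depth acts as
#' the prior (variance \eqn{r+q}), the current frame as the measurement
#' (variance `r`), so each output frame is
#' \deqn{\hat z_t = z_{t-1} + K (z_t - z_{t-1}),\quad K = (r+q)/(2r+q).}
#' Large `r` relative to `q` pulls spurious single-frame depth spikes
#' towards the previous frame; `q >> r` trusts the measurements and leaves
#' the sequence unchanged. The first frame is passed through.
#'
#' @param depth_maps List of `depth_map` objects (or numeric matrices) on a
#'   common grid, in time order.
#' @param q Process variance (um^2).
#' @param r Measurement variance (um^2).
#' @return List of the same length and classes, temporally filtered.
#' @export
temporal_kalman <- function(depth_maps, q = 25, r = 400) {
  stopifnot(length(depth_maps) >= 1, q >= 0, r >= 0)
  if (length(depth_maps) == 1) {
    warning("single frame: temporal filter is the identity")
    return(depth_maps)
  }
  get_depth <- function(d) if (inherits(d, "depth_map")) d$depth_um else d
  gain <- (r + q) / (2 * r + q)
  out <- depth_maps
  prev <- get_depth(depth_maps[[1]])
  for (t in 2:length(depth_maps)) {
    cur <- get_depth(depth_maps[[t]])
    stopifnot(identical(dim(cur), dim(prev)))
    both <- is.finite(cur) & is.finite(prev)
    filt <- cur
    filt[both] <- prev[both] + gain * (cur[both] - prev[both])
    if (inherits(out[[t]], "depth_map")) {
      out[[t]]$depth_um <- filt
    } else {
      out[[t]] <- filt
    }
    prev <- cur
  }
  out
}

#' Extract a 26-point 3D midline skeleton
#'
#' The mask is thinned to a binary skeleton, short spurs are pruned, and the
#' longest geodesic path between endpoints gives the 2D midline from nose to
#' tail. Depth is sampled along it as the median over the worm's local
#' cross-section, a smoothing spline is fitted to the 3D coordinates, and
#' the curve is resampled at 26 equally spaced arc-length positions.
#' Endpoint ordering follows temporal continuity with `prev` (first frame:
#' arbitrary, flagged via the `head_assigned` attribute).
#'
#' @param mask A `seg_mask` or logical matrix.
#' @param depth A `depth_map` (or numeric depth matrix in um).
#' @param optics An [lf_optics()] (defaulting to the sweep optics carried by
#'   `depth`) fixing the lateral scale in um.
#' @param n_points Number of skeleton points (26 points / 25 segments).
#' @param spar Fixed smoothing parameter of [stats::smooth.spline()].
#' @param prune_len Spur-pruning length in pixels.
#' @param prev Previous frame's skeleton (tibble) for head continuity; or
#'   `flip = TRUE` to force a flip.
#' @param flip Reverse point order after continuity resolution.
#' @param length_band_um Sanity band for total arc length (warning outside).
#' @return Tibble with columns `point` (0-based, nose first), `x_um`,
#'   `y_um`, `z_um`; attributes `total_length_um`, `head_assigned`.
#' @export
extract_midline <- function(mask, depth, optics = NULL, n_points = 26,
                            spar = 0.6, prune_len = 6, prev = NULL,
                            flip = FALSE, length_band_um = c(200, 1500)) {
  m <- if (inherits(mask, "seg_mask")) mask$mask else mask
  z <- if (inherits(depth, "depth_map")) depth$depth_um else depth
  if (is.null(optics) && inherits(depth, "depth_map")) {
    optics <- depth$sweep$optics
  }
  stopifnot(inherits(optics, "lf_optics"))
  stopifnot(identical(dim(m), dim(z)))
  if (any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)])) {
    warning("mask touches the image border")
  }
  skel <- prune_spurs(skeletonize_mask(m), prune_len)
  if (sum(skeleton_graph(skel)$degree <= 1) > 2) stop("branched skeleton")
  path <- skeleton_longest_path(skel)
  if (is.null(path) || nrow(path) < 4) stop("midline too short")
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1)))
  # thinning retreats from the tips by about one body radius; extend each
  # end by following the medial (distance-transform) ridge, which tracks
  # curved tails that a straight-line march would exit early
  extend_end <- function(path) {
    k <- min(6, nrow(path))
    dir <- path[1, ] - path[k, ]
    dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
    pos <- path[1, ]
    ext <- NULL
    for (step_i in seq_len(50)) {
      best <- NULL
      for (ang in seq(-60, 60, by = 15) * pi / 180) {
        cd <- c(
          cos(ang) * dir[1] - sin(ang) * dir[2],
          sin(ang) * dir[1] + cos(ang) * dir[2]
        )
        cand <- pos + cd
        pi_ <- round(cand)
        if (pi_[1] < 1 || pi_[1] > nrow(m) || pi_[2] < 1 ||
          pi_[2] > ncol(m) || !m[pi_[1], pi_[2]]) {
          next
        }
        sc <- dm[pi_[1], pi_[2]] + 0.5 * sum(cd * dir)
        if (is.null(best) || sc > best$sc) {
          best <- list(pos = cand, dir = cd, sc = sc)
        }
      }
      if (is.null(best)) break
      pos <- best$pos
      dir <- dir + best$dir
      dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
      ext <- rbind(best$pos, ext)
    }
    if (!is.null(ext)) rbind(ext, path) else path
  }
  path <- extend_end(path)
  path <- extend_end(path[nrow(path):1, , drop = FALSE])
  path <- path[nrow(path):1, , drop = FALSE]
  # median depth over the local cross-section at each midline pixel
  ip <- round(path)
  zs <- numeric(nrow(path))
  for (i in seq_len(nrow(path))) {
    r <- max(1, ceiling(dm[ip[i, 1], ip[i, 2]]))
    i0 <- max(1, ip[i, 1] - r)
    i1 <- min(nrow(m), ip[i, 1] + r)
    j0 <- max(1, ip[i, 2] - r)
    j1 <- min(ncol(m), ip[i, 2] + r)
    win_m <- m[i0:i1, j0:j1]
    win_z <- z[i0:i1, j0:j1]
    vals <- win_z[win_m & is.finite(win_z)]
    zs[i] <- if (length(vals)) median(vals) else NA_real_
  }
  ok <- is.finite(zs)
  if (sum(ok) < 4) stop("depth undefined along the midline")
  pitch_um <- sample_pitch_um(optics)
  xs <- (path[, 1] - 1 - (nrow(m) - 1) / 2) * pitch_um
  ys <- (path[, 2] - 1 - (ncol(m) - 1) / 2) * pitch_um
  s2d <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  fitc <- function(v, keep) {
    sp <- smooth.spline(s2d[keep], v[keep], spar = spar)
    function(s) predict(sp, s)$y
  }
  fx <- fitc(xs, rep(TRUE, length(xs)))
  fy <- fitc(ys, rep(TRUE, length(ys)))
  fz <- fitc(zs, ok)
  sd_ <- seq(0, max(s2d), length.out = 20 * n_points)
  cx <- fx(sd_)
  cy <- fy(sd_)
  cz <- fz(sd_)
  arc <- c(0, cumsum(sqrt(diff(cx)^2 + diff(cy)^2 + diff(cz)^2)))
  total <- max(arc)
  if (total < length_band_um[1] || total > length_band_um[2]) {
    warning(sprintf("total arc length %.0f um outside sanity band", total))
  }
  tgt <- seq(0, total, length.out = n_points)
  pts <- cbind(
    approx(arc, cx, xout = tgt)$y,
    approx(arc, cy, xout = tgt)$y,
    approx(arc, cz, xout = tgt)$y
  )
  head_assigned <- FALSE
  if (!is.null(prev)) {
    pm <- as.matrix(prev[, c("x_um", "y_um", "z_um")])
    if (nrow(pm) == nrow(pts)) {
      d_fwd <- sum((pts - pm)^2)
      d_rev <- sum((pts[nrow(pts):1, ] - pm)^2)
      if (d_rev < d_fwd) pts <- pts[nrow(pts):1, ]
      head_assigned <- TRUE
    }
  }
  if (flip) pts <- pts[nrow(pts):1, ]
  out <- tibble::tibble(
    point = seq_len(n_points) - 1,
    x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3]
  )
  attr(out, "total_length_um") <- total
  attr(out, "head_assigned") <- head_assigned
  out
}

#' Segment angle representation of a 3D skeleton
#'
#' Each of the 25 segments is described by an azimuthal angle `theta`
#' (direction in the (x, y) plane, unwrapped along the body) and a polar
#' angle `phi` (elevation out of the (x, y) plane; 0 = planar). Both vectors
#' are mean-zeroed over the body length, making the representation invariant
#' to global in-plane rotation and to rigid motion; the removed means,
#' segment lengths and origin are kept as attributes so
#' [angles_to_skeleton()] can rebuild the coordinates exactly.
#'
#' @param skeleton Tibble or data frame with columns `x_um`, `y_um`, `z_um`
#'   (ordered, nose first).
#' @return Tibble with columns `segment` (1-based), `theta`, `phi`;
#'   attributes `mean_theta`, `mean_phi`, `seg_lengths_um`, `origin_um`.
#' @export
skeleton_angles <- function(skeleton) {
  sk <- as.matrix(as.data.frame(skeleton)[, c("x_um", "y_um", "z_um")])
  d <- diff(sk)
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) stop("zero-length segment")
  theta <- unwrap_angles(atan2(d[, 2], d[, 1]))
  phi <- asin(pmin(pmax(d[, 3] / len, -1), 1))
  out <- tibble::tibble(
    segment = seq_len(nrow(d)),
    theta = theta - mean(theta),
    phi = phi - mean(phi)
  )
  attr(out, "mean_theta") <- mean(theta)
  attr(out, "mean_phi") <- mean(phi)
  attr(out, "seg_lengths_um") <- len
  attr(out, "origin_um") <- sk[1, ]
  out
}

#' Rebuild skeleton coordinates from segment angles
#'
#' Inverse of [skeleton_angles()]: restores the removed angle means,
#' converts each segment's (theta, phi) back to a unit tangent and
#' integrates with the stored segment lengths from the stored origin.
#'
#' @param angles Tibble from [skeleton_angles()] (or with columns `theta`,
#'   `phi`) with the reconstruction attributes, or explicit arguments.
#' @param mean_theta,mean_phi Angle means to restore.
#' @param seg_lengths_um Segment lengths.
#' @param origin_um Position of the first point.
#' @return Tibble with columns `point`, `x_um`, `y_um`, `z_um`.
#' @export
angles_to_skeleton <- function(angles,
                               mean_theta = attr(angles, "mean_theta"),
                               mean_phi = attr(angles, "mean_phi"),
                               seg_lengths_um = attr(angles, "seg_lengths_um"),
                               origin_um = attr(angles, "origin_um")) {
  origin_um <- unname(as.numeric(origin_um))
  theta <- angles$theta + mean_theta
  phi <- angles$phi + mean_phi
  tx <- cos(phi) * cos(theta)
  ty <- cos(phi) * sin(theta)
  tz <- sin(phi)
  pts <- rbind(
    origin_um,
    matrix(origin_um, length(theta), 3, byrow = TRUE) +
      apply(cbind(tx, ty, tz) * seg_lengths_um, 2, cumsum)
  )
  dimnames(pts) <- NULL
  tibble::tibble(
    point = seq_len(nrow(pts)) - 1,
    x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3]
  )
}
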