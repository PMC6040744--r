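#' Microlens lattice parameters
#'
#' Geometry of the tiled subimage mosaic on the sensor: pitch (camera pixels
#' per subimage), in-plane orientation and the offset from the image origin
#' to one subimage centre (0-based pixel coordinates).
#'
#' @param pitch Subimage pitch in pixels (> 1).
#' @param orientation Lattice rotation in radians (|orientation| < pi/4).
#' @param offset Length-2 numeric, 0-based pixel position of a subimage
#'   centre.
#' @return An object of class `lf_lattice`.
#' @export
lf_lattice <- function(pitch, orientation = 0, offset = c(0, 0)) {
  pitch <- unname(as.numeric(pitch))
  orientation <- unname(as.numeric(orientation))
  stopifnot(pitch > 1, abs(orientation) < pi / 4, length(offset) == 2)
  structure(
    list(
      pitch = pitch, orientation = orientation,
      offset = as.numeric(offset)
    ),
    class = "lf_lattice"
  )
}

#' @export
print.lf_lattice <- function(x, ...) {
  cat(sprintf(
    "<lf_lattice> pitch %.3f px, orientation %.3f deg, offset (%.2f, %.2f)\n",
    x$pitch, x$orientation * 180 / pi, x$offset[1], x$offset[2]
  ))
  invisible(x)
}

# Smooth-edged disc-tile template evaluated at every pixel of an
# nx x ny image for given lattice parameters; values in [0, 1].
lattice_mask_soft <- function(nx, ny, pitch, orientation, offset,
                              radius_frac = 0.48) {
  px <- matrix(seq_len(nx) - 1, nx, ny)
  py <- matrix(seq_len(ny) - 1, nx, ny, byrow = TRUE)
  co <- cos(-orientation)
  si <- sin(-orientation)
  rx <- co * (px - offset[1]) - si * (py - offset[2])
  ry <- si * (px - offset[1]) + co * (py - offset[2])
  lx <- rx - pitch * round(rx / pitch)
  ly <- ry - pitch * round(ry / pitch)
  r <- sqrt(lx^2 + ly^2)
  pmin(pmax(radius_frac * pitch - r + 0.5, 0), 1)
}

#' Estimate the microlens lattice from a raw mosaic
#'
#' An initial estimate of pitch and orientation is obtained from the
#' prominent peaks of the 2D Fourier transform of the raw image; the full
#' parameter set (pitch, orientation, offset) is then fine-tuned by
#' maximising the 2D cross-correlation between a disc-tile template and the
#' normalised image.
#'
#' @param raw Numeric matrix containing at least 10 x 10 subimages.
#' @return An [lf_lattice()].
#' @export
estimate_lattice <- function(raw) {
  nx <- nrow(raw)
  ny <- ncol(raw)
  img <- (raw - mean(raw)) / (sd(raw) + .Machine$double.eps)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  spec <- Mod(fft(img * outer(hann(nx), hann(ny))))
  fx <- c(seq(0, floor(nx / 2)), seq(-ceiling(nx / 2) + 1, -1)) / nx
  fy <- c(seq(0, floor(ny / 2)), seq(-ceiling(ny / 2) + 1, -1)) / ny
  FX <- matrix(fx, nx, ny)
  FY <- matrix(fy, nx, ny, byrow = TRUE)
  fr <- sqrt(FX^2 + FY^2)
  ang <- atan2(FY, FX)
  # fundamental along +x axis: |angle| < 5 deg, at least 10 periods
  cand <- which(abs(ang) < 5 * pi / 180 & fr >= 10 / min(nx, ny) & fr <= 1 / 3)
  if (length(cand) == 0) {
    stop("no microlens lattice detected")
  }
  pk <- cand[which.max(spec[cand])]
  if (spec[pk] < 10 * median(spec[fr > 10 / min(nx, ny)])) {
    stop("no microlens lattice detected")
  }
  # sub-bin peak position by parabolic interpolation along each axis
  ij <- arrayInd(pk, dim(spec))
  par_shift <- function(vals) {
    den <- vals[1] - 2 * vals[2] + vals[3]
    if (den == 0) 0 else 0.5 * (vals[1] - vals[3]) / den
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dx <- par_shift(spec[wrap(ij[1] + (-1:1), nx), ij[2]])
  dy <- par_shift(spec[ij[1], wrap(ij[2] + (-1:1), ny)])
  fx0 <- fx[ij[1]] + dx / nx
  fy0 <- fy[ij[2]] + dy / ny
  pitch0 <- 1 / sqrt(fx0^2 + fy0^2)
  orient0 <- atan2(fy0, fx0)
  # coarse offset search on a 1 px grid, then joint refinement
  score <- function(p) {
    m <- lattice_mask_soft(nx, ny, p[1], p[2], p[3:4])
    mean(img * (m - mean(m)))
  }
  grid <- expand.grid(
    ox = seq(0, pitch0, by = 1),
    oy = seq(0, pitch0, by = 1)
  )
  sc <- apply(grid, 1, function(g) score(c(pitch0, orient0, g[1], g[2])))
  best <- grid[which.max(sc), ]
  opt <- optim(
    c(pitch0, orient0, best$ox, best$oy), score,
    control = list(
      fnscale = -1, maxit = 1000, reltol = 1e-12,
      parscale = c(0.05, 0.002, 0.2, 0.2)
    )
  )
  p <- opt$par
  # polish: intensity centroids of each whole subimage regressed on the
  # lattice indices; the linear fit gives pitch, orientation and offset to
  # a small fraction of a pixel, free of template-shape bias
  pol <- tryCatch(centroid_polish(raw, p), error = function(e) NULL)
  if (!is.null(pol)) p <- pol
  lf_lattice(
    pitch = p[1], orientation = p[2],
    offset = p[3:4] %% p[1]
  )
}

# Least-squares refinement of lattice parameters from subimage intensity
# centroids. `p` = c(pitch, orientation, ox, oy).
centroid_polish <- function(raw, p) {
  nx <- nrow(raw)
  ny <- ncol(raw)
  pitch <- p[1]
  co <- cos(p[2])
  si <- sin(p[2])
  h <- floor(pitch / 2)
  imax <- ceiling(max(nx, ny) / pitch)
  rows <- NULL
  bg <- stats::quantile(raw, 0.05)
  for (i in -imax:imax) {
    for (j in -imax:imax) {
      cx <- co * i * pitch - si * j * pitch + p[3]
      cy <- si * i * pitch + co * j * pitch + p[4]
      x0 <- round(cx) - h
      y0 <- round(cy) - h
      if (x0 < 1 || y0 < 1 || x0 + 2 * h > nx || y0 + 2 * h > ny) next
      tile <- raw[x0:(x0 + 2 * h), y0:(y0 + 2 * h)] - bg
      tile[tile < 0] <- 0
      w <- sum(tile)
      if (w <= 0) next
      gx <- sum(tile * (row(tile) - 1)) / w + x0 - 1
      gy <- sum(tile * (col(tile) - 1)) / w + y0 - 1
      rows <- rbind(rows, c(i, j, gx, gy))
    }
  }
  if (is.null(rows) || nrow(rows) < 12) {
    return(NULL)
  }
  fx <- lm(rows[, 3] ~ rows[, 1] + rows[, 2])
  fy <- lm(rows[, 4] ~ rows[, 1] + rows[, 2])
  a1 <- c(coef(fx)[2], coef(fy)[2]) # lattice vector along i
  a2 <- c(coef(fx)[3], coef(fy)[3]) # lattice vector along j
  pitch_new <- unname((sqrt(sum(a1^2)) + sqrt(sum(a2^2))) / 2)
  orient_new <- unname((atan2(a1[2], a1[1]) + atan2(a2[2], a2[1]) - pi / 2) / 2)
  c(pitch_new, orient_new, unname(coef(fx)[1]), unname(coef(fy)[1]))
}

#' Resample a raw mosaic into a rectified 4D light field
#'
#' Bilinear resampling onto an axis-aligned lattice with `round(pitch)`
#' pixels per subimage; sample spacing `pitch / round(pitch)` with a
#' Jacobian intensity correction, so the total radiance over valid samples
#' is conserved. Only lattice sites whose whole subimage lies inside the
#' image are kept (truncation at the borders is reported with a warning when
#' the lattice extends beyond the image).
#'
#' @param raw Numeric matrix (vignetting-corrected mosaic).
#' @param lattice An [lf_lattice()].
#' @param optics An [lf_optics()].
#' @return A [light_field()].
#' @export
resample_to_4d <- function(raw, lattice, optics) {
  stopifnot(inherits(lattice, "lf_lattice"), inherits(optics, "lf_optics"))
  n <- round(lattice$pitch)
  if (n < 3) {
    stop("pitch below 3 px: too few angular samples")
  }
  nx <- nrow(raw)
  ny <- ncol(raw)
  half <- lattice$pitch / 2
  co <- cos(lattice$orientation)
  si <- sin(lattice$orientation)
  # lens index ranges whose rotated subimage footprint stays inside
  imax <- floor((max(nx, ny) / lattice$pitch) + 1)
  iseq <- seq(-imax, imax)
  centres_x <- outer(iseq * lattice$pitch * co, -iseq * lattice$pitch * si, `+`) +
    lattice$offset[1]
  centres_y <- outer(iseq * lattice$pitch * si, iseq * lattice$pitch * co, `+`) +
    lattice$offset[2]
  marg <- half * (abs(co) + abs(si))
  inside <- centres_x >= marg - 0.5 & centres_x <= nx - 1 - marg + 0.5 &
    centres_y >= marg - 0.5 & centres_y <= ny - 1 - marg + 0.5
  any_partial <- any((centres_x > -half & centres_x < nx - 1 + half &
    centres_y > -half & centres_y < ny - 1 + half) & !inside)
  if (any_partial) {
    warning("lattice extends outside image; truncating to whole subimages")
  }
  ii <- apply(inside, 1, any)
  jj <- apply(inside, 2, any)
  if (!any(ii) || !any(jj)) {
    stop("no complete subimage inside the image")
  }
  ir <- range(which(ii))
  jr <- range(which(jj))
  li <- iseq[seq(ir[1], ir[2])]
  lj <- iseq[seq(jr[1], jr[2])]
  nlx <- length(li)
  nly <- length(lj)
  s <- lattice$pitch / n
  uc <- centred_coords(n) * s
  # full 4D sample grid, built angular-major then permuted to (x, y, u, v)
  gr <- expand.grid(u = uc, xi = li * lattice$pitch, v = uc, yj = lj * lattice$pitch)
  lx <- gr$xi + gr$u
  ly <- gr$yj + gr$v
  sx <- co * lx - si * ly + lattice$offset[1]
  sy <- si * lx + co * ly + lattice$offset[2]
  vals <- bilinear_at(raw, sx, sy) * s^2
  arr <- array(vals, dim = c(n, nlx, n, nly))
  arr <- aperm(arr, c(2, 4, 1, 3))
  arr[is.na(arr)] <- 0
  arr[arr < 0] <- 0
  light_field(arr, optics)
}
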