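# Fusion of the two depth cues into a single per-pixel depth map by
# discrete MRF optimisation over the sweep's depth labels:
#
#   E(z) = sum_p [ w_d(p) |z_p - z_d(p)| + w_c(p) |z_p - z_c(p)| ]
#        + lambda * sum_{p~q} min(|z_p - z_q|, tau)
#
# with label-unit distances, weights from normalised cue confidences and a
# truncated-linear smoothness prior on the 4-neighbour grid. Chains are
# solved exactly by dynamic programming with O(L) lower-envelope messages;
# narrow instances are solved exactly via joint column states; general
# grids use alternating scanline DP with an ICM polish.

# message(g)(z) = min_z' g(z') + lambda * min(|z - z'|, tau)
dt_message <- function(g, lambda, tau) {
  L <- length(g)
  d <- g
  if (L > 1) {
    for (i in 2:L) d[i] <- min(d[i], d[i - 1] + lambda)
    for (i in (L - 1):1) d[i] <- min(d[i], d[i + 1] + lambda)
  }
  pmin(d, min(g) + lambda * tau)
}

# Exact 1D chain: unary is L x n (columns = chain nodes).
solve_chain_dp <- function(unary, lambda, tau) {
  L <- nrow(unary)
  n <- ncol(unary)
  if (n == 1) {
    return(which.min(unary[, 1]))
  }
  f <- matrix(0, L, n)
  f[, 1] <- unary[, 1]
  for (t in 2:n) {
    f[, t] <- unary[, t] + dt_message(f[, t - 1], lambda, tau)
  }
  z <- integer(n)
  z[n] <- which.min(f[, n])
  pair <- function(zi) lambda * pmin(abs(seq_len(L) - zi), tau)
  for (t in (n - 1):1) {
    z[t] <- which.min(f[, t] + pair(z[t + 1]))
  }
  z
}

# Exact solver for narrow grids: joint states over the shorter dimension.
solve_mrf_exact_narrow <- function(unary, footprint, lambda, tau) {
  L <- dim(unary)[3]
  nr <- nrow(footprint)
  nc <- ncol(footprint)
  transposed <- FALSE
  if (nr > nc) {
    unary <- aperm(unary, c(2, 1, 3))
    footprint <- t(footprint)
    nr <- nrow(footprint)
    nc <- ncol(footprint)
    transposed <- TRUE
  }
  states <- as.matrix(expand.grid(rep(list(seq_len(L)), nr)))
  S <- nrow(states)
  # per-column state costs: unaries + vertical (within-column) pairwise
  colcost <- matrix(0, S, nc)
  for (j in seq_len(nc)) {
    for (r in seq_len(nr)) {
      if (!footprint[r, j]) next
      colcost[, j] <- colcost[, j] + unary[r, j, ][states[, r]]
    }
    if (nr > 1) {
      for (r in seq_len(nr - 1)) {
        if (footprint[r, j] && footprint[r + 1, j]) {
          colcost[, j] <- colcost[, j] +
            lambda * pmin(abs(states[, r] - states[, r + 1]), tau)
        }
      }
    }
  }
  trans <- function(j) {
    # S x S transition cost between column j and j+1
    tc <- matrix(0, S, S)
    for (r in seq_len(nr)) {
      if (footprint[r, j] && footprint[r, j + 1]) {
        tc <- tc + lambda * pmin(abs(outer(states[, r], states[, r], `-`)), tau)
      }
    }
    tc
  }
  f <- matrix(0, S, nc)
  back <- matrix(1L, S, nc)
  f[, 1] <- colcost[, 1]
  if (nc == 1) {
    zs <- which.min(f[, 1])
    lab <- matrix(states[zs, ], nr, 1)
    if (transposed) lab <- t(lab)
    return(lab)
  }
  for (j in 2:nc) {
    tc <- trans(j - 1)
    tot <- tc + f[, j - 1] # recycles f down columns: tot[s', s] layout
    back[, j] <- apply(tot, 2, which.min)
    f[, j] <- colcost[, j] + tot[cbind(back[, j], seq_len(S))]
  }
  zs <- integer(nc)
  zs[nc] <- which.min(f[, nc])
  for (j in (nc - 1):1) zs[j] <- back[zs[j + 1], j + 1]
  lab <- matrix(NA_integer_, nr, nc)
  for (j in seq_len(nc)) lab[, j] <- states[zs[j], ]
  if (transposed) lab <- t(lab)
  lab
}

mrf_energy <- function(lab, unary, footprint, lambda, tau) {
  e <- 0
  nr <- nrow(footprint)
  nc <- ncol(footprint)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!footprint[i, j]) next
      e <- e + unary[i, j, lab[i, j]]
      if (i < nr && footprint[i + 1, j]) {
        e <- e + lambda * min(abs(lab[i, j] - lab[i + 1, j]), tau)
      }
      if (j < nc && footprint[i, j + 1]) {
        e <- e + lambda * min(abs(lab[i, j] - lab[i, j + 1]), tau)
      }
    }
  }
  e
}

# Alternating scanline DP + ICM for general grids.
solve_mrf_scanline <- function(unary, footprint, lambda, tau, init,
                               n_iter = 5) {
  L <- dim(unary)[3]
  nr <- nrow(footprint)
  nc <- ncol(footprint)
  lab <- init
  lseq <- seq_len(L)
  for (it in seq_len(n_iter)) {
    # horizontal pass: each row is a chain conditioned on rows above/below
    for (i in seq_len(nr)) {
      js <- which(footprint[i, ])
      if (length(js) == 0) next
      un <- matrix(0, L, length(js))
      for (m in seq_along(js)) {
        j <- js[m]
        u <- unary[i, j, ]
        if (i > 1 && footprint[i - 1, j]) {
          u <- u + lambda * pmin(abs(lseq - lab[i - 1, j]), tau)
        }
        if (i < nr && footprint[i + 1, j]) {
          u <- u + lambda * pmin(abs(lseq - lab[i + 1, j]), tau)
        }
        un[, m] <- u
      }
      # contiguous runs share the chain; gaps decouple
      runs <- split(seq_along(js), cumsum(c(1, diff(js) != 1)))
      for (rn in runs) {
        lab[i, js[rn]] <- solve_chain_dp(un[, rn, drop = FALSE], lambda, tau)
      }
    }
    # vertical pass
    for (j in seq_len(nc)) {
      is <- which(footprint[, j])
      if (length(is) == 0) next
      un <- matrix(0, L, length(is))
      for (m in seq_along(is)) {
        i <- is[m]
        u <- unary[i, j, ]
        if (j > 1 && footprint[i, j - 1]) {
          u <- u + lambda * pmin(abs(lseq - lab[i, j - 1]), tau)
        }
        if (j < nc && footprint[i, j + 1]) {
          u <- u + lambda * pmin(abs(lseq - lab[i, j + 1]), tau)
        }
        un[, m] <- u
      }
      runs <- split(seq_along(is), cumsum(c(1, diff(is) != 1)))
      for (rn in runs) {
        lab[is[rn], j] <- solve_chain_dp(un[, rn, drop = FALSE], lambda, tau)
      }
    }
  }
  # ICM polish
  for (sweep in 1:10) {
    changed <- FALSE
    for (i in seq_len(nr)) {
      for (j in which(footprint[i, ])) {
        u <- unary[i, j, ]
        if (i > 1 && footprint[i - 1, j]) {
          u <- u + lambda * pmin(abs(lseq - lab[i - 1, j]), tau)
        }
        if (i < nr && footprint[i + 1, j]) {
          u <- u + lambda * pmin(abs(lseq - lab[i + 1, j]), tau)
        }
        if (j > 1 && footprint[i, j - 1]) {
          u <- u + lambda * pmin(abs(lseq - lab[i, j - 1]), tau)
        }
        if (j < nc && footprint[i, j + 1]) {
          u <- u + lambda * pmin(abs(lseq - lab[i, j + 1]), tau)
        }
        znew <- which.min(u)
        if (znew != lab[i, j]) {
          lab[i, j] <- znew
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

#' Fuse defocus and correspondence depth estimates with an MRF
#'
#' Minimises an energy with confidence-weighted L1 data terms towards each
#' cue's depth label and a truncated-linear smoothness prior over the
#' 4-neighbour grid, over the discrete depth labels of the sweep. Chains and
#' narrow grids are solved exactly by dynamic programming; larger grids by
#' alternating scanline DP from a confidence-weighted-mean initialisation,
#' with an ICM polish.
#'
#' @param dd,dc `cue_depth` objects from [cue_extrema()] (defocus and
#'   correspondence) on a common grid and sweep.
#' @param footprint Logical matrix: pixels to solve for.
#' @param lambda Smoothness weight (default 0.5).
#' @param tau Truncation of the smoothness cost, in labels (default 10).
#' @param solver `"auto"`, `"exact"` (narrow instances only) or
#'   `"scanline"`.
#' @return An object of class `depth_map`: `depth_um` (NA outside the
#'   footprint), `confidence`, `label`, `footprint`, `reliable`, `sweep`.
#' @export
combine_depth <- function(dd, dc, footprint, lambda = 0.5, tau = 10,
                          solver = c("auto", "exact", "scanline")) {
  stopifnot(inherits(dd, "cue_depth"), inherits(dc, "cue_depth"))
  solver <- match.arg(solver)
  stopifnot(identical(dim(dd$label), dim(dc$label)))
  stopifnot(identical(dim(footprint), dim(dd$label)))
  if (!any(footprint)) stop("empty footprint")
  nr <- nrow(footprint)
  nc_ <- ncol(footprint)
  K <- length(dd$sweep$alphas)
  wd <- ifelse(is.finite(dd$confidence) & dd$reliable, dd$confidence, 0)
  wc <- ifelse(is.finite(dc$confidence) & dc$reliable, dc$confidence, 0)
  tot <- wd + wc
  wd <- ifelse(tot > 0, wd / tot, 0)
  wc <- ifelse(tot > 0, wc / tot, 0)
  ld <- dd$label
  lc <- dc$label
  unary <- array(0, dim = c(nr, nc_, K))
  lseq <- seq_len(K)
  for (k in lseq) {
    u <- matrix(0, nr, nc_)
    ok <- is.finite(ld) & wd > 0
    u[ok] <- u[ok] + wd[ok] * abs(k - ld[ok])
    ok <- is.finite(lc) & wc > 0
    u[ok] <- u[ok] + wc[ok] * abs(k - lc[ok])
    unary[, , k] <- u
  }
  use_exact <- solver == "exact" ||
    (solver == "auto" &&
      (min(nr, nc_) == 1 || (min(nr, nc_) <= 3 && K^min(nr, nc_) <= 512)))
  if (use_exact && min(nr, nc_) > 1 && K^min(nr, nc_) > 4096) {
    stop("instance too large for the exact solver")
  }
  lab <- if (use_exact) {
    solve_mrf_exact_narrow(unary, footprint, lambda, tau)
  } else {
    init0 <- round(
      ifelse(tot > 0,
        (wd * ifelse(is.finite(ld), ld, 0) +
          wc * ifelse(is.finite(lc), lc, 0)),
        (K + 1) / 2
      )
    )
    init0 <- matrix(pmin(pmax(init0, 1), K), nr, nc_)
    solve_mrf_scanline(unary, footprint, lambda, tau, init0)
  }
  depth <- matrix(NA_real_, nr, nc_)
  depth[footprint] <- dd$sweep$depths_um[lab[footprint]]
  label <- matrix(NA_integer_, nr, nc_)
  label[footprint] <- lab[footprint]
  fused_conf <- wd * ifelse(is.finite(dd$confidence), dd$confidence, 0) +
    wc * ifelse(is.finite(dc$confidence), dc$confidence, 0)
  fused_conf[!footprint] <- NA_real_
  reliable <- (dd$reliable | dc$reliable) & footprint
  structure(
    list(
      depth_um = depth, confidence = fused_conf, label = label,
      footprint = footprint, reliable = reliable, sweep = dd$sweep
    ),
    class = "depth_map"
  )
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf(
    "<depth_map> %d x %d px, %d footprint px, depth %.1f .. %.1f um\n",
    nrow(x$depth_um), ncol(x$depth_um), sum(x$footprint),
    suppressWarnings(min(x$depth_um, na.rm = TRUE)),
    suppressWarnings(max(x$depth_um, na.rm = TRUE))
  ))
  invisible(x)
}

#' Estimate a depth map from a rectified light field
#'
#' Convenience composition of the full single-frame pipeline: defocus and
#' correspondence responses over the sweep, per-cue extrema and confidences,
#' MRF fusion, and (optionally) division by a calibration gradient so that
#' corrected estimates regress on known depth with unit slope.
#'
#' @param lf A [light_field()].
#' @param sweep A [depth_sweep()].
#' @param footprint Logical matrix of pixels to estimate (default:
#'   full frame).
#' @param window Cue window size in pixels (default 5).
#' @param lambda,tau MRF parameters, see [combine_depth()].
#' @param gradient Optional calibration gradient (see
#'   [calibrate_depth_scale()]); estimates are divided by it.
#' @param cap Confidence cap, see [cue_extrema()].
#' @return A `depth_map`.
#' @export
estimate_depth <- function(lf, sweep, footprint = NULL, window = 5,
                           lambda = 0.5, tau = 10, gradient = NULL,
                           cap = 100) {
  d <- dim(lf$radiance)
  if (is.null(footprint)) footprint <- matrix(TRUE, d[1], d[2])
  vols <- sweep_cue_volumes(lf, sweep,
    w_d = window, w_c = window,
    footprint = if (all(footprint)) NULL else footprint
  )
  dd <- cue_extrema(vols$defocus, cap = cap)
  dc <- cue_extrema(vols$correspondence, cap = cap)
  dm <- combine_depth(dd, dc, footprint, lambda = lambda, tau = tau)
  if (!is.null(gradient)) {
    stopifnot(is.numeric(gradient), gradient != 0)
    dm$depth_um <- dm$depth_um / gradient
  }
  dm
}

#' Calibrate the depth scale against known displacements
#'
#' Ordinary least squares of estimated versus known depth,
#' `estimated = gradient * known + intercept`. Downstream correction divides
#' estimates by the gradient, so that corrected estimates regress on known
#' depth with unit slope.
#'
#' @param estimated,known Numeric vectors of depths in micrometres
#'   (>= 3 points, distinct known values).
#' @return An object of class `depth_calibration` with fields `gradient`,
#'   `intercept_um`, `r_squared`, `rmse_um`, `n` and the fitted `model`.
#' @export
calibrate_depth_scale <- function(estimated, known) {
  ok <- is.finite(estimated) & is.finite(known)
  estimated <- estimated[ok]
  known <- known[ok]
  if (length(known) < 3) stop("need at least 3 calibration points")
  if (length(unique(known)) < 2) stop("known depths must be distinct")
  fit <- lm(estimated ~ known)
  res <- fit$residuals
  structure(
    list(
      gradient = unname(coef(fit)[2]),
      intercept_um = unname(coef(fit)[1]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      rmse_um = sqrt(mean(res^2)),
      n = length(known),
      model = fit,
      data = tibble::tibble(known_um = known, estimated_um = estimated)
    ),
    class = "depth_calibration"
  )
}

#' @export
print.depth_calibration <- function(x, ...) {
  cat(sprintf(
    "<depth_calibration> gradient %.4f, intercept %.2f um, R^2 %.5f, RMSE %.2f um (n = %d)\n",
    x$gradient, x$intercept_um, x$r_squared, x$rmse_um, x$n
  ))
  invisible(x)
}

#' @rdname calibrate_depth_scale
#' @param x A `depth_calibration` object.
#' @param ... Unused.
#' @export
tidy.depth_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("gradient", "intercept_um"),
    estimate = c(x$gradient, x$intercept_um)
  )
}

#' @rdname calibrate_depth_scale
#' @export
glance.depth_calibration <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, rmse_um = x$rmse_um,
    gradient = x$gradient, intercept_um = x$intercept_um, n = x$n
  )
}
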