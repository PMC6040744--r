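# Defocus and correspondence depth cues over a refocusing sweep.
#
# Both cues derive from the same per-alpha angular statistics of the sheared
# light field: the view-integrated image feeds the defocus response (local
# |Laplacian| sharpness, maximal in focus), the angular standard deviation
# feeds the correspondence response (view disagreement, minimal in focus).

new_response_volume <- function(values, cue, window, sweep) {
  structure(
    list(values = values, cue = cue, window = window, sweep = sweep),
    class = "response_volume"
  )
}

#' @export
print.response_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<response_volume> %s cue, %d x %d px, %d sweep steps (window %d)\n",
    x$cue, d[1], d[2], d[3], x$window
  ))
  invisible(x)
}

# Shared evaluation of both cue volumes from one kernel pass.
# `footprint`, when supplied, restricts evaluation to its dilation
# (radius `dilate_px`); outside pixels are NA.
sweep_cue_volumes <- function(lf, sweep, w_d = 5, w_c = 5,
                              footprint = NULL, dilate_px = 10) {
  stopifnot(inherits(lf, "light_field"), inherits(sweep, "depth_sweep"))
  if (length(sweep$alphas) < 1) stop("empty sweep")
  d <- dim(lf$radiance)
  if (w_d > d[1] || w_d > d[2] || w_c > d[1] || w_c > d[2]) {
    stop("window larger than image")
  }
  # responses are registered to the native object frame (the alpha
  # rescaling of the refocused photograph is undone) so that a pixel's
  # response profile tracks a single object point across the sweep
  st <- lf_sweep_stats(lf, sweep$alphas, object_frame = TRUE)
  nk <- length(sweep$alphas)
  roi <- if (!is.null(footprint)) {
    stopifnot(identical(dim(footprint), d[1:2]))
    k <- disc_kernel(dilate_px)
    EBImage::imageData(EBImage::dilate(EBImage::Image(footprint * 1), k)) > 0
  } else {
    matrix(TRUE, d[1], d[2])
  }
  dvol <- array(NA_real_, dim = c(d[1], d[2], nk))
  cvol <- array(NA_real_, dim = c(d[1], d[2], nk))
  for (k in seq_len(nk)) {
    cnt <- matrix(st$count[, , k], d[1], d[2])
    mu <- matrix(
      ifelse(cnt > 0, st$sum[, , k] / pmax(cnt, 1), NA_real_),
      d[1], d[2]
    )
    lap <- abs(laplacian5(mu))
    dk <- box_mean(lap, w_d)
    sig2 <- matrix(st$sumsq[, , k], d[1], d[2]) / pmax(cnt, 1) - mu^2
    sig <- sqrt(pmax(sig2, 0))
    sig[cnt < 2] <- NA_real_
    ck <- box_mean(sig, w_c)
    dk[!roi] <- NA_real_
    ck[!roi] <- NA_real_
    dvol[, , k] <- dk
    cvol[, , k] <- ck
  }
  list(
    defocus = new_response_volume(dvol, "defocus", w_d, sweep),
    correspondence = new_response_volume(cvol, "correspondence", w_c, sweep)
  )
}

#' Defocus depth response over a sweep
#'
#' For each sweep point the light field is refocused and view-integrated,
#' and the response is the absolute 5-point Laplacian of the refocused image
#' averaged over a `window x window` neighbourhood:
#' \eqn{D_\alpha(x,y) = |W_D|^{-1} \sum_{W_D} |\Delta_{xy} \bar L_\alpha|}.
#' Sharpness is maximal when the shear matches the object's depth.
#'
#' @param lf A [light_field()].
#' @param sweep A [depth_sweep()].
#' @param window Odd box size in pixels (default 5).
#' @param footprint Optional logical mask; responses are evaluated only
#'   inside its dilation (radius `dilate_px`).
#' @param dilate_px Dilation radius for `footprint`.
#' @return A `response_volume`.
#' @export
defocus_response <- function(lf, sweep, window = 5, footprint = NULL,
                             dilate_px = 10) {
  stopifnot(window >= 3, window %% 2 == 1)
  sweep_cue_volumes(lf, sweep,
    w_d = window, w_c = 1,
    footprint = footprint, dilate_px = dilate_px
  )$defocus
}

#' Correspondence depth response over a sweep
#'
#' For each sweep point, the per-pixel angular standard deviation
#' \eqn{\sigma_\alpha} over valid views of the sheared light field
#' (population normalisation,
#' \eqn{\sigma_\alpha^2 = N^{-1} \sum_{u,v} (L_\alpha - \bar L_\alpha)^2}),
#' box-averaged over a `window x window` neighbourhood. View agreement is
#' maximal (response minimal) when the shear matches the object's depth.
#'
#' @inheritParams defocus_response
#' @param window Odd box size in pixels (default 5; 1 = no spatial pooling).
#' @return A `response_volume`. Pixels with fewer than 2 valid views are NA.
#' @export
correspondence_response <- function(lf, sweep, window = 5, footprint = NULL,
                                    dilate_px = 10) {
  stopifnot(window >= 1, window %% 2 == 1)
  sweep_cue_volumes(lf, sweep,
    w_d = min(5, window), w_c = window,
    footprint = footprint, dilate_px = dilate_px
  )$correspondence
}

#' Extract per-pixel cue optima and confidences from a response volume
#'
#' The optimum is the argmax over the sweep for the defocus cue and the
#' argmin for the correspondence cue. Confidence is the peak-ratio to the
#' next-best strict local extremum of the response profile (inverted for
#' correspondence so that larger is always better, hence confidence >= 1);
#' profiles with no second extremum get the cap, flat profiles get
#' confidence 1 and are flagged unreliable.
#'
#' @param resp A `response_volume`.
#' @param cap Maximal confidence value.
#' @param eps Flattening tolerance for strict extrema.
#' @return An object of class `cue_depth`: matrices `label` (sweep index),
#'   `alpha_star`, `depth_um`, `confidence`, `reliable`.
#' @export
cue_extrema <- function(resp, cap = 100, eps = 1e-12) {
  stopifnot(inherits(resp, "response_volume"))
  d <- dim(resp$values)
  nk <- d[3]
  if (nk < 3) stop("sweep length must be >= 3")
  maximise <- resp$cue == "defocus"
  m <- matrix(resp$values, d[1] * d[2], nk)
  if (!maximise) m <- -m
  valid <- rowSums(is.finite(m)) == nk
  lab <- rep(NA_integer_, nrow(m))
  conf <- rep(NA_real_, nrow(m))
  rel <- rep(FALSE, nrow(m))
  if (any(valid)) {
    mv <- m[valid, , drop = FALSE]
    best <- max.col(mv, ties.method = "first")
    bestval <- mv[cbind(seq_len(nrow(mv)), best)]
    flat <- (bestval - apply(mv, 1, min)) <= eps
    # strict local maxima (after eps-flattening), ends included
    peak <- matrix(FALSE, nrow(mv), nk)
    peak[, 1] <- mv[, 1] > mv[, 2] + eps
    peak[, nk] <- mv[, nk] > mv[, nk - 1] + eps
    if (nk > 2) {
      inner <- 2:(nk - 1)
      peak[, inner] <- mv[, inner, drop = FALSE] >
        mv[, inner - 1, drop = FALSE] + eps &
        mv[, inner, drop = FALSE] > mv[, inner + 1, drop = FALSE] + eps
    }
    peak[cbind(seq_len(nrow(mv)), best)] <- FALSE
    second <- suppressWarnings(apply(
      ifelse(peak, mv, -Inf), 1, max
    ))
    cf <- rep(NA_real_, nrow(mv))
    has2 <- is.finite(second)
    if (maximise) {
      cf[has2] <- bestval[has2] / pmax(second[has2], eps)
    } else {
      # response values are negated; invert the ratio on the originals
      cf[has2] <- pmax(-second[has2], eps) / pmax(-bestval[has2], eps)
    }
    cf[!has2] <- cap
    cf <- pmin(pmax(cf, 1), cap)
    cf[flat] <- 1
    lab[valid] <- best
    conf[valid] <- cf
    rel[valid] <- !flat
  }
  label <- matrix(lab, d[1], d[2])
  alpha_star <- matrix(resp$sweep$alphas[lab], d[1], d[2])
  depth <- matrix(resp$sweep$depths_um[lab], d[1], d[2])
  structure(
    list(
      label = label, alpha_star = alpha_star, depth_um = depth,
      confidence = matrix(conf, d[1], d[2]),
      reliable = matrix(rel, d[1], d[2]),
      cue = resp$cue, sweep = resp$sweep
    ),
    class = "cue_depth"
  )
}

#' @export
print.cue_depth <- function(x, ...) {
  cat(sprintf(
    "<cue_depth> %s cue, %d x %d px (%.0f%% reliable)\n",
    x$cue, nrow(x$label), ncol(x$label),
    100 * mean(x$reliable, na.rm = TRUE)
  ))
  invisible(x)
}
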