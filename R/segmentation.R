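# Lateral segmentation of the worm in the on-axis view, plus the binary
# skeleton machinery (Zhang-Suen thinning, spur pruning, longest path)
# shared by midline extraction and self-occlusion detection.

#' Segment the worm footprint in an on-axis view
#'
#' Adaptive local-mean thresholding, largest-component selection,
#' morphological hole filling and closing, followed by a region-based
#' (Chan-Vese-type) active-contour refinement with a fixed iteration
#' budget.
#'
#' @param image Numeric matrix (on-axis pinhole view).
#' @param window Odd side of the local-mean window (pixels).
#' @param offset Threshold offset above the local mean, as a fraction of the
#'   image dynamic range.
#' @param min_area Minimal component area in pixels ("no worm found" below).
#' @param close_radius Disc radius for morphological closing.
#' @param refine_iter Active-contour iterations (0 disables refinement).
#' @param mu Contour-length (curvature) weight of the refinement.
#' @return An object of class `seg_mask`: `mask` (logical), `contour`
#'   (ordered boundary coordinates), `area`.
#' @export
segment_worm <- function(image, window = 15, offset = 0.01, min_area = 200,
                         close_radius = 3, refine_iter = 30, mu = 0.1) {
  stopifnot(is.matrix(image), length(image) > 0)
  rng <- range(image, finite = TRUE)
  if (diff(rng) <= 0) stop("no worm found")
  img <- (image - rng[1]) / diff(rng)
  w2 <- (window - 1) / 2
  bw <- EBImage::imageData(EBImage::thresh(
    EBImage::Image(img),
    w = w2, h = w2, offset = offset
  )) > 0
  bw <- largest_component(bw)
  if (sum(bw) < min_area) stop("no worm found")
  bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  bw <- EBImage::imageData(
    EBImage::closing(EBImage::Image(bw * 1), disc_kernel(close_radius))
  ) > 0
  if (refine_iter > 0) {
    bw <- chan_vese_refine(img, bw, n_iter = refine_iter, mu = mu)
  }
  bw <- largest_component(bw)
  bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  if (sum(bw) < min_area) stop("no worm found")
  new_seg_mask(bw)
}

new_seg_mask <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  structure(
    list(
      mask = mask,
      contour = if (length(oc)) oc[[which.max(lengths(oc))]] else NULL,
      area = sum(mask)
    ),
    class = "seg_mask"
  )
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf(
    "<seg_mask> %d x %d px, area %d px\n",
    nrow(x$mask), ncol(x$mask), x$area
  ))
  invisible(x)
}

# Region-based active-contour refinement of a binary mask (Chan-Vese-type):
# evolve a signed-distance level set under the two-region data force and a
# curvature penalty, fixed iteration budget, periodic re-initialisation.
chan_vese_refine <- function(img, mask, n_iter = 30, mu = 0.1, dt = 0.5) {
  sdist <- function(m) {
    inside <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1)))
    outside <- EBImage::imageData(EBImage::distmap(EBImage::Image((!m) * 1)))
    inside - outside
  }
  phi <- sdist(mask)
  eps <- 1.5
  for (it in seq_len(n_iter)) {
    inside <- phi > 0
    if (!any(inside) || all(inside)) break
    c1 <- mean(img[inside])
    c2 <- mean(img[!inside])
    gx <- (rbind(phi[-1, , drop = FALSE], phi[nrow(phi), ]) -
      rbind(phi[1, ], phi[-nrow(phi), , drop = FALSE])) / 2
    gy <- (cbind(phi[, -1, drop = FALSE], phi[, ncol(phi)]) -
      cbind(phi[, 1], phi[, -ncol(phi), drop = FALSE])) / 2
    gnorm <- sqrt(gx^2 + gy^2) + 1e-8
    nxx <- gx / gnorm
    nyy <- gy / gnorm
    div <- (rbind(nxx[-1, , drop = FALSE], nxx[nrow(nxx), ]) -
      rbind(nxx[1, ], nxx[-nrow(nxx), , drop = FALSE])) / 2 +
      (cbind(nyy[, -1, drop = FALSE], nyy[, ncol(nyy)]) -
        cbind(nyy[, 1], nyy[, -ncol(nyy), drop = FALSE])) / 2
    force <- -(img - c1)^2 + (img - c2)^2
    delta <- eps / (pi * (eps^2 + phi^2))
    phi <- phi + dt * delta * (mu * div + force)
    if (it %% 10 == 0) phi <- sdist(phi > 0)
  }
  phi > 0
}

# --- binary skeleton machinery -------------------------------------------

# Zhang-Suen thinning of a logical matrix.
thin_mask <- function(mask) {
  m <- mask
  pad <- function(x) {
    out <- matrix(FALSE, nrow(x) + 2, ncol(x) + 2)
    out[2:(nrow(x) + 1), 2:(ncol(x) + 1)] <- x
    out
  }
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      p <- pad(m)
      nr <- nrow(m)
      nc <- ncol(m)
      ci <- 2:(nr + 1)
      cj <- 2:(nc + 1)
      p2 <- p[ci - 1, cj]
      p3 <- p[ci - 1, cj + 1]
      p4 <- p[ci, cj + 1]
      p5 <- p[ci + 1, cj + 1]
      p6 <- p[ci + 1, cj]
      p7 <- p[ci + 1, cj - 1]
      p8 <- p[ci, cj - 1]
      p9 <- p[ci - 1, cj - 1]
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- Reduce(`+`, lapply(1:8, function(k) {
        (!seqs[[k]]) & seqs[[k + 1]]
      }))
      if (step == 0) {
        cond <- m & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Thin a mask to a 1-px skeleton curve.
skeletonize_mask <- function(mask) thin_mask(mask)

# Skeleton pixel graph with reduced adjacency: 8-connectivity minus
# diagonal "triangle shortcut" edges (a diagonal edge is dropped when the
# two pixels share an orthogonal skeleton neighbour). Zhang-Suen skeletons
# contain staircase corners whose spurious 8-adjacencies would otherwise
# masquerade as junctions; on the reduced graph open curves have clean
# degree-1 endpoints and degree-2 interiors.
skeleton_graph <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  id <- matrix(0L, nrow(skel), ncol(skel))
  if (nrow(px)) id[px] <- seq_len(nrow(px))
  at <- function(i, j) {
    ok <- i >= 1 & i <= nrow(skel) & j >= 1 & j <= ncol(skel)
    out <- integer(length(i))
    out[ok] <- id[cbind(i[ok], j[ok])]
    out
  }
  adj <- vector("list", nrow(px))
  for (k in seq_len(nrow(px))) {
    i <- px[k, 1]
    j <- px[k, 2]
    orth <- at(c(i - 1, i + 1, i, i), c(j, j, j - 1, j + 1))
    diag_ <- at(c(i - 1, i - 1, i + 1, i + 1), c(j - 1, j + 1, j - 1, j + 1))
    di <- c(-1, -1, 1, 1)
    dj <- c(-1, 1, -1, 1)
    keep <- diag_ > 0
    for (m in which(keep)) {
      # drop the diagonal edge if an orthogonal skeleton pixel bridges it
      if (at(i + di[m], j) > 0 || at(i, j + dj[m]) > 0) keep[m] <- FALSE
    }
    adj[[k]] <- c(orth[orth > 0], diag_[keep])
  }
  list(px = px, id = id, adj = adj, degree = lengths(adj))
}

# Remove spur branches shorter than prune_len; returns the pruned skeleton.
prune_spurs <- function(skel, prune_len = 6) {
  repeat {
    g <- skeleton_graph(skel)
    ends <- which(g$degree == 1)
    if (length(ends) == 0 || nrow(g$px) == 0) break
    removed_any <- FALSE
    for (e in ends) {
      walk <- walk_graph(g, e, max_len = prune_len + 1)
      if (!walk$hit_junction || length(walk$nodes) > prune_len) next
      skel[g$px[walk$nodes, , drop = FALSE]] <- FALSE
      removed_any <- TRUE
      break # graph is stale after a removal; rebuild
    }
    if (!removed_any) break
  }
  skel
}

# Walk along degree-<=2 nodes from an endpoint until a junction, another
# endpoint, or max_len nodes. Returns visited node ids (excluding the
# junction) and whether a junction was reached.
walk_graph <- function(g, start, max_len = Inf) {
  cur <- start
  prev <- 0L
  nodes <- integer(0)
  hit_junction <- FALSE
  while (length(nodes) < max_len) {
    nodes <- c(nodes, cur)
    nxt <- setdiff(g$adj[[cur]], prev)
    if (length(nxt) == 0) break
    nxt <- nxt[1]
    if (g$degree[nxt] >= 3) {
      hit_junction <- TRUE
      break
    }
    prev <- cur
    cur <- nxt
  }
  list(nodes = nodes, hit_junction = hit_junction)
}

# Longest geodesic path between skeleton endpoints (BFS twice on the
# reduced-adjacency graph). Returns an ordered n x 2 matrix of pixel
# indices.
skeleton_longest_path <- function(skel) {
  g <- skeleton_graph(skel)
  if (nrow(g$px) == 0) {
    return(NULL)
  }
  bfs <- function(s) {
    dist <- rep(NA_integer_, nrow(g$px))
    par <- rep(NA_integer_, nrow(g$px))
    dist[s] <- 0L
    q <- s
    head <- 1L
    while (head <= length(q)) {
      v <- q[head]
      head <- head + 1L
      for (w in g$adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          par[w] <- v
          q <- c(q, w)
        }
      }
    }
    list(dist = dist, par = par)
  }
  ends <- which(g$degree <= 1)
  s0 <- if (length(ends)) ends[1] else 1L
  b1 <- bfs(s0)
  e1 <- which.max(replace(b1$dist, is.na(b1$dist), -1L))
  b2 <- bfs(e1)
  e2 <- which.max(replace(b2$dist, is.na(b2$dist), -1L))
  path <- integer(0)
  v <- e2
  while (!is.na(v)) {
    path <- c(path, v)
    v <- b2$par[v]
  }
  g$px[path, , drop = FALSE]
}

#' Flag a self-occluded (coiled or crossing) posture
#'
#' A frame is flagged when the thinned skeleton of the mask is not a simple
#' open curve (a cycle, or more than two endpoints after pruning short
#' spurs), or when the mask area is inconsistent with a single non-
#' overlapping tube (area / (midline length x modal width) above
#' `ratio_max`). Flagged frames are excluded from skeletonization.
#'
#' @param mask A `seg_mask` or logical matrix.
#' @param prune_len Spur-pruning length in pixels.
#' @param ratio_max Maximal area ratio for a simple tube.
#' @return Logical scalar.
#' @export
flag_self_occlusion <- function(mask, prune_len = 6, ratio_max = 1.5) {
  m <- if (inherits(mask, "seg_mask")) mask$mask else mask
  if (!any(m)) {
    return(FALSE)
  }
  skel <- prune_spurs(skeletonize_mask(m), prune_len)
  if (!any(skel)) {
    return(TRUE)
  }
  g <- skeleton_graph(skel)
  n_ends <- sum(g$degree <= 1)
  if (n_ends == 0 && sum(skel) >= 8) {
    return(TRUE) # cycle: coiled loop
  }
  if (n_ends > 2) {
    return(TRUE) # branched: crossing body parts
  }
  path <- skeleton_longest_path(skel)
  if (is.null(path) || nrow(path) < 2) {
    return(FALSE)
  }
  len <- sum(sqrt(rowSums(diff(path)^2)))
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1)))
  width <- 2 * median(dm[skel])
  ratio <- sum(m) / max(len * width, 1)
  ratio > ratio_max
}
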