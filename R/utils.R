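# Small image helpers shared across modules. Images are numeric matrices
# indexed [x, y] (row = x), matching the 4D radiance array layout.

# Bilinear interpolation of matrix `img` at continuous 0-based coordinates
# (xi, yi); returns NA outside the support or where any corner is NA.
bilinear_at <- function(img, xi, yi) {
  nx <- nrow(img)
  ny <- ncol(img)
  out <- rep(NA_real_, length(xi))
  ok <- xi >= 0 & yi >= 0 & xi <= nx - 1 & yi <= ny - 1 &
    is.finite(xi) & is.finite(yi)
  if (!any(ok)) {
    return(out)
  }
  x0 <- pmin(floor(xi[ok]), nx - 2)
  y0 <- pmin(floor(yi[ok]), ny - 2)
  fx <- xi[ok] - x0
  fy <- yi[ok] - y0
  i00 <- cbind(x0 + 1, y0 + 1)
  v <- img[i00] * (1 - fx) * (1 - fy) +
    img[i00 + c(1, 0)] * fx * (1 - fy) +
    img[i00 + c(0, 1)] * (1 - fx) * fy +
    img[i00 + c(1, 1)] * fx * fy
  out[ok] <- v
  out
}

# 5-point discrete Laplacian with replicate padding at the borders.
laplacian5 <- function(img) {
  nx <- nrow(img)
  ny <- ncol(img)
  if (nx < 2 || ny < 2) {
    return(img * 0)
  }
  up <- img[c(1, seq_len(nx - 1)), , drop = FALSE]
  dn <- img[c(seq(2, nx), nx), , drop = FALSE]
  lf <- img[, c(1, seq_len(ny - 1)), drop = FALSE]
  rt <- img[, c(seq(2, ny), ny), drop = FALSE]
  up + dn + lf + rt - 4 * img
}

# Mean over a w x w window, renormalised at the borders (mean over the
# in-bounds part of the window). NA cells are excluded from the mean;
# windows with no finite cell give NA.
box_mean <- function(img, w) {
  stopifnot(w >= 1, w %% 2 == 1)
  if (w > nrow(img) || w > ncol(img)) {
    stop("window larger than image")
  }
  if (w == 1) {
    return(img)
  }
  val <- img
  bad <- !is.finite(val)
  val[bad] <- 0
  cnt <- matrix(as.numeric(!bad), nrow(img), ncol(img))
  h <- (w - 1) / 2
  sum_w <- function(m) {
    cs <- apply(m, 2, cumsum)
    cs <- rbind(0, cs)
    n <- nrow(m)
    hi <- pmin(seq_len(n) + h, n) + 1
    lo <- pmax(seq_len(n) - h, 1)
    m2 <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
    cs2 <- t(apply(m2, 1, cumsum))
    cs2 <- cbind(0, cs2)
    nc <- ncol(m)
    hic <- pmin(seq_len(nc) + h, nc) + 1
    loc <- pmax(seq_len(nc) - h, 1)
    cs2[, hic, drop = FALSE] - cs2[, loc, drop = FALSE]
  }
  s <- sum_w(val)
  n <- sum_w(cnt)
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

# Centred 0-based coordinate ladder of length n: 0..n-1 minus (n-1)/2.
centred_coords <- function(n) seq_len(n) - 1 - (n - 1) / 2

# Largest connected component of a binary matrix (8-connectivity).
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) {
    return(matrix(FALSE, nrow(mask), ncol(mask)))
  }
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

disc_kernel <- function(r) {
  d <- 2 * r + 1
  k <- matrix(0, d, d)
  idx <- expand.grid(x = seq_len(d), y = seq_len(d))
  k[as.matrix(idx)] <- as.numeric((idx$x - r - 1)^2 + (idx$y - r - 1)^2 <= r^2)
  k
}
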