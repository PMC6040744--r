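# Rhodonea (rose-curve) model of 3D swimming: the paired theta/phi
# projection amplitudes of one eigenworm trace a rose
#   a^theta(t) = A cos[k(a t + c)] cos[a t + c]
#   a^phi(t)   = A cos[k(a t + c)] sin[a t + c]
# where (a t + c) is the slowly rotating orientation of the oscillation
# plane (body roll) and k is the number of undulation cycles per roll.

rhodonea_pair <- function(t, A, k, a, c) {
  env <- A * cos(k * (a * t + c))
  list(theta = env * cos(a * t + c), phi = env * sin(a * t + c))
}

#' Generate a rhodonea amplitude pair
#'
#' @param t Time vector (s).
#' @param A Amplitude.
#' @param k Undulation-to-roll frequency ratio.
#' @param a Roll angular rate (rad/s).
#' @param c Roll phase (rad).
#' @param noise_sd SD of additive Gaussian noise.
#' @return Tibble: `time_s`, `a_theta`, `a_phi`.
#' @export
generate_rhodonea <- function(t, A = 1, k = 8.5, a = pi, c = 0,
                              noise_sd = 0) {
  p <- rhodonea_pair(t, A, k, a, c)
  tibble::tibble(
    time_s = t,
    a_theta = p$theta + rnorm(length(t), sd = noise_sd),
    a_phi = p$phi + rnorm(length(t), sd = noise_sd)
  )
}

# Joint least-squares fit of one (a_theta, a_phi) pair. Initialisation:
# the squared radius A^2 cos^2[k(at+c)] oscillates at 2ka -> dominant FFT
# peak gives k*a; k is then scanned on a coarse grid with closed-form A and
# a coarse phase scan, and the best candidate refined with nlsLM.
fit_rhodonea_pair <- function(t, a_theta, a_phi,
                              k_grid = seq(0.5, 20, by = 0.25)) {
  ok <- is.finite(t) & is.finite(a_theta) & is.finite(a_phi)
  t <- t[ok]
  y1 <- a_theta[ok]
  y2 <- a_phi[ok]
  if (length(t) < 16 || (sd(y1) + sd(y2)) < 1e-12) {
    stop("no oscillation detected")
  }
  dt <- median(diff(t))
  r2 <- y1^2 + y2^2
  sp <- Mod(fft(r2 - mean(r2)))[seq_len(floor(length(t) / 2))]
  freqs <- (seq_along(sp) - 1) / (length(t) * dt) # cycles/s
  pk <- which.max(sp[-1]) + 1
  ka_est <- pi * freqs[pk] # rad/s: half the 2*k*a peak
  if (!is.finite(ka_est) || ka_est <= 0) stop("no oscillation detected")
  sse_of <- function(A, k, a, c) {
    p <- rhodonea_pair(t, A, k, a, c)
    sum((y1 - p$theta)^2 + (y2 - p$phi)^2)
  }
  # The SSE landscape oscillates in `a` with period ~2*pi/(k*T); each k is
  # scanned with a fine inner grid on a (around the spectral estimate) and
  # a coarse phase scan, amplitude solved in closed form.
  cands <- list()
  c_grid <- seq(0, 2 * pi, length.out = 17)[-17]
  for (k in k_grid) {
    a0 <- ka_est / k
    best_k <- NULL
    for (a_try in a0 * seq(0.96, 1.04, length.out = 17)) {
      for (c_try in c_grid) {
        b1 <- cos(k * (a_try * t + c_try)) * cos(a_try * t + c_try)
        b2 <- cos(k * (a_try * t + c_try)) * sin(a_try * t + c_try)
        den <- sum(b1^2 + b2^2)
        if (den < 1e-12) next
        A_try <- max(sum(y1 * b1 + y2 * b2) / den, 0)
        sse <- sse_of(A_try, k, a_try, c_try)
        if (is.null(best_k) || sse < best_k$sse) {
          best_k <- list(A = A_try, k = k, a = a_try, c = c_try, sse = sse)
        }
      }
    }
    if (!is.null(best_k)) cands[[length(cands) + 1]] <- best_k
  }
  if (length(cands) == 0) stop("no oscillation detected")
  ord <- order(vapply(cands, `[[`, numeric(1), "sse"))
  best <- cands[[ord[1]]]
  dat <- data.frame(
    t = rep(t, 2), y = c(y1, y2), ch = rep(0:1, each = length(t))
  )
  for (i in ord[seq_len(min(3, length(ord)))]) {
    st <- cands[[i]]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * cos(k * (a * t + c)) *
          ((1 - ch) * cos(a * t + c) + ch * sin(a * t + c)),
        data = dat,
        start = list(A = st$A, k = st$k, a = st$a, c = st$c),
        lower = c(A = 0, k = 1e-3, a = 1e-6, c = -2 * pi),
        upper = c(A = Inf, k = 50, a = Inf, c = 4 * pi),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      cf <- as.list(coef(fit))
      sse <- sse_of(cf$A, cf$k, cf$a, cf$c)
      if (sse < best$sse) best <- c(cf, list(sse = sse))
    }
  }
  best$c <- best$c %% (2 * pi)
  best
}

#' Fit the rhodonea swimming model to eigenworm projections
#'
#' Least-squares fit of the paired theta/phi projection amplitudes of each
#' requested mode to the rose-curve model, fitted independently per mode and
#' summarised by the mean and SD of the roll-frequency ratio `k` across
#' modes.
#'
#' @param projections Tibble from [project_series()] (columns `time_s`,
#'   `mode`, `a_theta`, `a_phi`).
#' @param modes Modes to fit (default 1:2).
#' @return Object of class `rhodonea_fit`: per-mode tibble `fits` (columns
#'   `mode`, `A`, `k`, `a`, `c`, `residual_norm`), `k_mean`, `k_sd`.
#' @export
fit_rhodonea <- function(projections, modes = 1:2) {
  stopifnot(all(c("time_s", "mode", "a_theta", "a_phi") %in%
    names(projections)))
  fits <- purrr::map_dfr(modes, function(m) {
    d <- projections[projections$mode == m, ]
    f <- fit_rhodonea_pair(d$time_s, d$a_theta, d$a_phi)
    tibble::tibble(
      mode = m, A = f$A, k = f$k, a = f$a, c = f$c,
      residual_norm = sqrt(f$sse)
    )
  })
  structure(
    list(
      fits = fits,
      k_mean = mean(fits$k), k_sd = sd(fits$k),
      projections = projections[projections$mode %in% modes, ]
    ),
    class = "rhodonea_fit"
  )
}

#' @export
print.rhodonea_fit <- function(x, ...) {
  cat(sprintf(
    "<rhodonea_fit> %d mode(s); k = %.2f +/- %.2f\n",
    nrow(x$fits), x$k_mean,
    if (is.na(x$k_sd)) 0 else x$k_sd
  ))
  print(x$fits)
  invisible(x)
}

#' @rdname fit_rhodonea
#' @param x A `rhodonea_fit`.
#' @param ... Unused.
#' @export
tidy.rhodonea_fit <- function(x, ...) x$fits

#' @rdname fit_rhodonea
#' @export
glance.rhodonea_fit <- function(x, ...) {
  tibble::tibble(k_mean = x$k_mean, k_sd = x$k_sd, n_modes = nrow(x$fits))
}
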