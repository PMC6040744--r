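# Eigenworm analysis: principal postural modes of mean-zeroed 25-element
# segment-angle vectors, a shared (azimuthal) projection basis, and
# explained-variance bookkeeping.

#' Assemble a posture ensemble matrix from angle tibbles
#'
#' Concatenates per-frame mean-zeroed angle vectors (one channel: theta or
#' phi) into the frames x segments matrix on which eigenworms are computed.
#'
#' @param angles Tibble with columns `frame`, `segment` and the channel
#'   column (`theta` or `phi`), e.g. from [skeleton_angles()] rows bound
#'   over frames, or `generate_locomotion()$angles`.
#' @param channel `"theta"` or `"phi"`.
#' @return Numeric matrix (frames x segments) with class
#'   `posture_ensemble`; row names are frame ids.
#' @export
posture_ensemble <- function(angles, channel = c("theta", "phi")) {
  channel <- match.arg(channel)
  stopifnot(all(c("frame", "segment", channel) %in% names(angles)))
  wide <- angles %>%
    select("frame", "segment", value = dplyr::all_of(channel)) %>%
    tidyr::pivot_wider(names_from = "segment", values_from = "value") %>%
    arrange(.data$frame)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$frame
  structure(m, class = c("posture_ensemble", class(m)), channel = channel)
}

#' Compute eigenworms from a posture ensemble
#'
#' Column-centred principal component analysis of the concatenated angle
#' matrix; the top `m` principal directions are the eigenworms. Each
#' eigenworm's sign is fixed so that its largest-magnitude element is
#' positive.
#'
#' @param ensemble Matrix (frames x segments) of mean-zeroed angle vectors
#'   (rows >= segments), e.g. from [posture_ensemble()].
#' @param m Number of modes to keep (<= number of segments).
#' @return Object of class `posture_basis`: `eigenworms` (segments x m,
#'   orthonormal columns), `variance_fraction` (descending, all
#'   components), `center` (ensemble column means), `channel`.
#' @export
compute_eigenworms <- function(ensemble, m = 4) {
  x <- unclass(ensemble)
  stopifnot(is.matrix(x), nrow(x) >= ncol(x), m >= 1, m <= ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) <= 0) stop("ensemble has zero variance after centring")
  rank_ <- sum(ev > ev[1] * 1e-12)
  if (m > rank_) {
    stop(sprintf("ensemble rank %d is below the requested %d modes", rank_, m))
  }
  basis <- pc$rotation[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(
    list(
      eigenworms = basis,
      variance_fraction = ev / sum(ev),
      center = pc$center,
      channel = attr(ensemble, "channel") %||% "theta"
    ),
    class = "posture_basis"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.posture_basis <- function(x, ...) {
  m <- ncol(x$eigenworms)
  cat(sprintf(
    "<posture_basis> %d eigenworms (%s), first %d capture %.1f%% of variance\n",
    m, x$channel, m, 100 * sum(x$variance_fraction[seq_len(m)])
  ))
  invisible(x)
}

#' @rdname compute_eigenworms
#' @param x A `posture_basis`.
#' @param ... Unused.
#' @export
tidy.posture_basis <- function(x, ...) {
  tibble::tibble(
    mode = rep(seq_len(ncol(x$eigenworms)), each = nrow(x$eigenworms)),
    segment = rep(seq_len(nrow(x$eigenworms)), ncol(x$eigenworms)),
    loading = as.vector(x$eigenworms)
  )
}

#' @rdname compute_eigenworms
#' @export
glance.posture_basis <- function(x, ...) {
  tibble::tibble(
    n_modes = ncol(x$eigenworms),
    variance_captured = sum(x$variance_fraction[seq_len(ncol(x$eigenworms))])
  )
}

#' Cumulative variance captured by the leading eigenworms
#'
#' @param basis A `posture_basis`.
#' @param n Number of leading modes.
#' @return Fraction in \[0, 1\].
#' @export
variance_captured <- function(basis, n = 4) {
  stopifnot(inherits(basis, "posture_basis"))
  stopifnot(n >= 1, n <= length(basis$variance_fraction))
  sum(basis$variance_fraction[seq_len(n)])
}

#' Project postures onto an eigenworm basis
#'
#' Amplitudes \eqn{a_i = e_i \cdot (x - \bar x)} of each angle vector on
#' each eigenworm. Both angle channels are usually projected onto the single
#' shared azimuthal basis.
#'
#' @param angles A numeric vector (one posture), a matrix (frames x
#'   segments), or a [posture_ensemble()].
#' @param basis A `posture_basis`.
#' @param center Mean vector to subtract before projecting (default: the
#'   basis's own ensemble mean; when projecting the other angle channel
#'   onto a shared basis, that channel's own mean is the appropriate
#'   choice).
#' @return Matrix of amplitudes (frames x modes); a vector input gives one
#'   row.
#' @export
project_posture <- function(angles, basis, center = basis$center) {
  stopifnot(inherits(basis, "posture_basis"))
  x <- if (is.matrix(angles)) unclass(angles) else matrix(angles, nrow = 1)
  if (ncol(x) != nrow(basis$eigenworms)) {
    stop("angle vector length does not match the basis")
  }
  sweep(x, 2, center) %*% basis$eigenworms
}

#' Eigenworm projection time series for both angle channels
#'
#' Projects the theta and phi angle vectors of every frame onto one shared
#' basis (by default the azimuthal set).
#'
#' @param angles Tibble with `frame`, `segment`, `theta`, `phi` columns (and
#'   optionally `time_s`).
#' @param basis A `posture_basis` (shared, azimuthal).
#' @param dt_s Frame interval used when `angles` lacks `time_s`.
#' @return Tibble: `frame`, `time_s`, `mode`, `a_theta`, `a_phi`.
#' @export
project_series <- function(angles, basis, dt_s = 0.05) {
  at <- project_posture(posture_ensemble(angles, "theta"), basis)
  # the shared basis carries the azimuthal ensemble mean; the polar
  # channel is centred on its own mean
  ens_phi <- posture_ensemble(angles, "phi")
  ap <- project_posture(ens_phi, basis, center = colMeans(unclass(ens_phi)))
  frames <- sort(unique(angles$frame))
  times <- if ("time_s" %in% names(angles)) {
    angles %>%
      dplyr::distinct(.data$frame, .data$time_s) %>%
      arrange(.data$frame) %>%
      pull(.data$time_s)
  } else {
    (frames - min(frames)) * dt_s
  }
  m <- ncol(at)
  tibble::tibble(
    frame = rep(frames, m),
    time_s = rep(times, m),
    mode = rep(seq_len(m), each = length(frames)),
    a_theta = as.vector(at),
    a_phi = as.vector(ap)
  )
}
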