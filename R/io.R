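# File interfaces: raw mosaics as (multipage) grayscale TIFF, optics
# configuration as YAML/JSON, depth maps as 32-bit float TIFF, rectified
# light fields as a flat binary container with a JSON sidecar.

#' Read a raw light field mosaic (multipage TIFF)
#'
#' When a `<path>.json` range sidecar (written by [write_lf_mosaic()]) is
#' present, values are restored to their original scale; otherwise raw
#' stored values are returned.
#'
#' @param path TIFF file (8/16-bit or float grayscale).
#' @return List of numeric matrices (one per page).
#' @export
read_lf_mosaic <- function(path) {
  sidecar <- paste0(path, ".json")
  scale <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    NULL
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = is.null(scale))
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    # readTIFF returns row-major [y, x]; transpose to [x, y]
    p <- t(p)
    if (!is.null(scale)) p <- p * (scale$max - scale$min) + scale$min
    p
  })
}

#' Write one or more images as a (multipage) TIFF
#'
#' TIFF samples are stored in the unit interval; values are mapped linearly
#' to `[0, 1]` and the original range recorded in a small JSON sidecar
#' (`<path>.json`) which [read_lf_mosaic()] uses to restore the scale.
#' Non-finite pixels are written as the minimum.
#'
#' @param images Matrix or list of matrices (`[x, y]` layout).
#' @param path Output file.
#' @param bits 16 (integer) or 32 (float) bits per sample.
#' @export
write_lf_mosaic <- function(images, path, bits = 16) {
  if (is.matrix(images)) images <- list(images)
  vals <- unlist(lapply(images, function(m) m[is.finite(m)]))
  lo <- min(vals, 0)
  hi <- max(vals, lo + 1)
  imgs <- lapply(images, function(m) {
    m[!is.finite(m)] <- lo
    t((m - lo) / (hi - lo))
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = bits, reduce = FALSE)
  jsonlite::write_json(list(min = lo, max = hi), paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an optics configuration (YAML or JSON)
#'
#' Recognised keys: `pitch_px`, `mla_focal_um`, `magnification`,
#' `pixel_size_um`, `frame_rate_hz`, `aperture_radius_frac` (missing keys
#' fall back to [lf_optics()] defaults).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return An [lf_optics()].
#' @export
read_optics <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  keys <- c(
    "pitch_px", "mla_focal_um", "magnification", "pixel_size_um",
    "frame_rate_hz", "aperture_radius_frac"
  )
  do.call(lf_optics, cfg[intersect(names(cfg), keys)])
}

#' Persist a rectified light field
#'
#' Writes the radiance as a flat little-endian float64 binary alongside a
#' JSON sidecar (`<path>.json`) recording dims, the angular mask and the
#' optics, so the container is readable without R.
#'
#' @param lf A [light_field()].
#' @param path Output path for the binary radiance (sidecar added).
#' @return `path`, invisibly.
#' @export
write_light_field <- function(lf, path) {
  stopifnot(inherits(lf, "light_field"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(lf$radiance), con, size = 8, endian = "little")
  meta <- list(
    dims = dim(lf$radiance),
    angular_mask = lf$angular_mask,
    optics = unclass(lf$optics),
    dtype = "float64-le"
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_light_field
#' @export
read_light_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(path, "rb")
  on.exit(close(con))
  rad <- array(
    readBin(con, "double", n = n, size = 8, endian = "little"),
    dim = meta$dims
  )
  light_field(
    rad, do.call(lf_optics, as.list(meta$optics)),
    matrix(as.logical(meta$angular_mask), meta$dims[3], meta$dims[4])
  )
}

#' Write a depth map as 32-bit float TIFFs
#'
#' Depth in micrometres (NaN outside the footprint) plus a companion
#' confidence image (`<stem>_confidence.tif`).
#'
#' @param dm A `depth_map`.
#' @param path Output TIFF path.
#' @export
write_depth_tiff <- function(dm, path) {
  stopifnot(inherits(dm, "depth_map"))
  write_lf_mosaic(dm$depth_um, path, bits = 32)
  write_lf_mosaic(
    ifelse(is.finite(dm$confidence), dm$confidence, 0),
    sub("(\\.tiff?)?$", "_confidence.tif", path),
    bits = 32
  )
  invisible(path)
}

#' Write skeleton time series as CSV
#'
#' Long format: `frame, time_s, point, x_um, y_um, z_um`.
#'
#' @param skeletons Skeleton tibble.
#' @param path Output CSV.
#' @export
write_skeletons_csv <- function(skeletons, path) {
  utils::write.csv(skeletons, path, row.names = FALSE)
  invisible(path)
}
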