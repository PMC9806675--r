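#' Write a calibrated image to TIFF with a JSON metadata sidecar
#'
#' Pages are written channel-fastest within each z slice. Intensities are
#' stored at integer bit depth (default 16-bit), so values must lie in
#' `[0, 2^bits - 1]`; non-integer values are quantized to the integer grid
#' with a warning. Calibration and channel names go to `<path>.json`, the
#' package's metadata sidecar (the installed TIFF writer exposes no tag or
#' description fields).
#'
#' @param image a [calibrated_image].
#' @param path output TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @param bits integer bit depth per sample: 8, 16 or 32.
#' @return `path`, invisibly.
#' @export
write_stack <- function(image, path, bits = 16L) {
  stopifnot(inherits(image, "calibrated_image"), bits %in% c(8L, 16L, 32L))
  maxval <- 2^bits - 1
  if (max(image$data) > maxval)
    stopf("intensities exceed %d-bit range; rescale before writing", bits)
  if (any(image$data != round(image$data)))
    warnf("non-integer intensities are quantized to the %d-bit grid on disk", bits)
  d <- dim(image$data)
  is3d <- is_3d(image)
  nz <- if (is3d) d[3] else 1L
  nc <- d[length(d)]
  pages <- vector("list", nz * nc)
  k <- 0L
  for (z in seq_len(nz)) for (c in seq_len(nc)) {
    k <- k + 1L
    pages[[k]] <- (if (is3d) image$data[, , z, c] else image$data[, , c]) / maxval
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  meta <- list(channel_names = image$channel_names,
               pixel_size_xy_um = image$pixel_size_xy,
               z_step_um = image$z_step,
               n_z = nz, n_channels = nc, bits = bits)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a TIFF/sidecar pair as a calibrated image
#'
#' Calibration priority: metadata sidecar (`<path>.json`, as written by
#' [write_stack()]) first, then TIFF resolution tags, then the explicit
#' override; if the sidecar and an override disagree, the override wins with
#' a warning. Without a sidecar all pages are interpreted as z-slices of a
#' single channel and intensities are returned as read (in `[0, 1]`).
#'
#' @param path TIFF file path.
#' @param pixel_size_override optional lateral calibration in micrometers.
#' @param z_step_override optional axial calibration in micrometers.
#' @return a [calibrated_image].
#' @export
read_stack <- function(path, pixel_size_override = NULL,
                       z_step_override = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL

  px <- NULL
  if (!is.null(meta$pixel_size_xy_um)) px <- as.numeric(meta$pixel_size_xy_um)
  if (is.null(px)) {
    xres <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit") %||% "inch"
    if (!is.null(xres) && is.finite(xres) && xres > 0) {
      um_per_unit <- switch(unit, inch = 25400, cm = 10000, 1e6)
      px <- um_per_unit / xres
    }
  }
  if (!is.null(pixel_size_override)) {
    if (!is.null(px) && abs(px - pixel_size_override) > 1e-9)
      warnf("calibration conflict (%g vs override %g um/px): override wins",
            px, pixel_size_override)
    px <- pixel_size_override
  }
  if (is.null(px))
    stopf("no pixel calibration in metadata and no override given: %s", path)

  nz <- as.integer(meta$n_z %||% length(pages))
  nc <- as.integer(meta$n_channels %||% 1L)
  if (nz * nc != length(pages))
    stopf("metadata claims %d pages but file has %d", nz * nc, length(pages))
  scale <- if (!is.null(meta$bits)) 2^as.integer(meta$bits) - 1 else 1
  chn <- if (!is.null(meta$channel_names))
    vapply(meta$channel_names, as.character, "") else NULL
  dyx <- dim(pages[[1]])[1:2]
  zs <- if (!is.null(meta$z_step_um)) as.numeric(meta$z_step_um) else NULL
  if (!is.null(z_step_override)) zs <- z_step_override

  arr <- array(0, c(dyx[1], dyx[2], nz, nc))
  k <- 0L
  for (z in seq_len(nz)) for (c in seq_len(nc)) {
    k <- k + 1L
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # tolerate greyscale-with-alpha
    # on-disk samples are integers; undo the writer's [0,1] scaling exactly
    arr[, , z, c] <- if (scale > 1) round(pg * scale) else pg
  }
  if (nz == 1L) {
    arr <- array(arr[, , 1L, ], c(dyx[1], dyx[2], nc))
    calibrated_image(arr, chn, px)
  } else {
    if (is.null(zs))
      stopf("3D stack without z-step metadata: pass z_step_override")
    calibrated_image(arr, chn, px, z_step = zs)
  }
}
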