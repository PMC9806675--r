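#' Calibrated multi-channel image
#'
#' The universal input container: a non-negative intensity array with named
#' channels and physical pixel/voxel calibration in micrometers. 2D images are
#' stored as `[y, x, channel]` arrays, 3D z-stacks as `[y, x, z, channel]`.
#' Pixel indices are 1-based; the physical position of pixel `(i, j)` is its
#' center, at `((j - 0.5), (i - 0.5)) * pixel_size_xy` in (x, y).
#'
#' @param data numeric matrix (one 2D channel), 3D array `[y, x, channel]`,
#'   or 4D array `[y, x, z, channel]`. Must be finite and non-negative.
#' @param channel_names character vector, one name per channel. Defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param pixel_size_xy lateral calibration, micrometers per pixel (> 0).
#' @param z_step axial calibration, micrometers per slice (> 0); required for
#'   (and only for) 4D input.
#' @return an object of class `calibrated_image`.
#' @examples
#' img <- calibrated_image(matrix(0, 8, 8), pixel_size_xy = 0.07)
#' img
#' @export
calibrated_image <- function(data, channel_names = NULL, pixel_size_xy,
                             z_step = NULL) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L))
    stopf("`data` must be [y,x,channel] or [y,x,z,channel]; got %d dims", nd)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stopf("intensities must be finite numbers")
  if (any(data < 0)) stopf("intensities must be >= 0")
  if (!is.numeric(pixel_size_xy) || length(pixel_size_xy) != 1 ||
      pixel_size_xy <= 0)
    stopf("pixel_size_xy must be a single positive number (micrometers)")
  is3d <- nd == 4L
  if (is3d) {
    if (is.null(z_step) || z_step <= 0)
      stopf("3D stacks require z_step > 0 (micrometers)")
  } else {
    z_step <- NULL
  }
  nc <- dim(data)[nd]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stopf("channel_names length (%d) != number of channels (%d)",
          length(channel_names), nc)
  storage.mode(data) <- "double"
  dim(data) <- unname(dim(data))
  dimnames(data) <- NULL
  structure(list(data = data, channel_names = as.character(channel_names),
                 pixel_size_xy = as.numeric(pixel_size_xy),
                 z_step = if (is3d) as.numeric(z_step) else NULL),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$data)
  if (is_3d(x)) {
    cat(sprintf("<calibrated_image 3D> %d x %d px, %d slices, %d channel(s)\n",
                d[1], d[2], d[3], d[4]))
    cat(sprintf("  voxel: %.4g x %.4g x %.4g um\n",
                x$pixel_size_xy, x$pixel_size_xy, x$z_step))
  } else {
    cat(sprintf("<calibrated_image 2D> %d x %d px, %d channel(s)\n",
                d[1], d[2], d[3]))
    cat(sprintf("  pixel: %.4g um\n", x$pixel_size_xy))
  }
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  rng <- range(x$data)
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Test whether a calibrated image is a 3D z-stack
#' @param image a [calibrated_image].
#' @return logical scalar.
#' @export
is_3d <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  length(dim(image$data)) == 4L
}

channel_index <- function(image, channel) {
  if (is.character(channel)) {
    i <- match(channel, image$channel_names)
    if (is.na(i)) stopf("unknown channel '%s' (have: %s)", channel,
                        paste(image$channel_names, collapse = ", "))
    return(i)
  }
  i <- as.integer(channel)
  if (i < 1 || i > length(image$channel_names)) stopf("channel index out of range")
  i
}

#' Extract one channel of a calibrated image as a plain array
#'
#' @param image a [calibrated_image].
#' @param channel channel name or index.
#' @return a `[y, x]` matrix (2D image) or `[y, x, z]` array (3D stack).
#' @export
get_channel <- function(image, channel) {
  i <- channel_index(image, channel)
  if (is_3d(image)) image$data[, , , i, drop = TRUE] else image$data[, , i, drop = TRUE]
}

#' Maximum-intensity z-projection
#'
#' Collapses a 3D z-stack to a 2D image by taking, per channel, the maximum
#' over z at every (y, x); lateral calibration is preserved. Tubule network
#' counts and other 2D readouts are taken on such projections.
#'
#' @param image a 3D [calibrated_image].
#' @return a 2D [calibrated_image].
#' @export
max_project <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!is_3d(image)) stopf("max_project: image is already 2D")
  d <- dim(image$data)
  out <- array(0, c(d[1], d[2], d[4]))
  for (c in seq_len(d[4])) {
    sl <- image$data[, , , c, drop = FALSE]
    dim(sl) <- d[1:3]
    m <- sl[, , 1]
    if (d[3] > 1) for (z in 2:d[3]) m <- pmax(m, sl[, , z])
    out[, , c] <- m
  }
  calibrated_image(out, image$channel_names, image$pixel_size_xy)
}

#' Normalize a count to a reference area
#'
#' Readouts such as tubule counts are reported per reference area (per 50,
#' 100 or 200 um^2 depending on the readout); this converts a raw count
#' measured in an ROI of known area.
#'
#' @param count non-negative count (or any additive quantity).
#' @param roi_area_um2 area of the measured ROI in um^2 (> 0).
#' @param ref_area_um2 reference area in um^2 (> 0), e.g. 50, 100, 200.
#' @return `count * ref_area_um2 / roi_area_um2`.
#' @examples
#' per_area(4, roi_area_um2 = 200, ref_area_um2 = 100)  # 2
#' @export
per_area <- function(count, roi_area_um2, ref_area_um2) {
  if (any(roi_area_um2 <= 0) || any(ref_area_um2 <= 0))
    stopf("per_area: areas must be positive")
  count * ref_area_um2 / roi_area_um2
}

#' Region of interest from a binary mask
#'
#' @param mask logical matrix (2D) marking the ROI foreground.
#' @param pixel_size_xy micrometers per pixel.
#' @return a list of class `roi` with elements `mask` and `area_um2`.
#' @export
roi_from_mask <- function(mask, pixel_size_xy) {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(list(mask = mask,
                 area_um2 = sum(mask) * pixel_size_xy^2),
            class = "roi")
}

#' Region of interest from a polygon
#'
#' Rasterizes a polygon given in continuous pixel coordinates (x right, y
#' down, pixel centers at half-integer positions k - 0.5) onto an image grid
#' by pixel-center inclusion.
#'
#' @param xy two-column matrix of polygon vertices in pixel coordinates.
#' @param dim_yx integer vector `c(ny, nx)` of the target grid.
#' @param pixel_size_xy micrometers per pixel.
#' @return a list of class `roi` with elements `mask`, `area_um2` and
#'   `polygon`.
#' @export
roi_from_polygon <- function(xy, dim_yx, pixel_size_xy) {
  stopifnot(is.matrix(xy), ncol(xy) == 2, nrow(xy) >= 3)
  ny <- dim_yx[1]; nx <- dim_yx[2]
  cx <- rep(seq_len(nx) - 0.5, each = ny)
  cy <- rep(seq_len(ny) - 0.5, times = nx)
  inside <- point_in_polygon(cx, cy, xy[, 1], xy[, 2])
  mask <- matrix(inside, ny, nx)
  r <- roi_from_mask(mask, pixel_size_xy)
  r$polygon <- xy
  r
}

## Even-odd rule point-in-polygon, vectorized over query points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
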