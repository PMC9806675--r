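## Shared rasterization machinery for the synthetic scene generators.
## Convention: continuous coordinates are in micrometers with the origin at
## the image corner; the center of pixel (row r, col c) sits at
## x = (c - 0.5) * px, y = (r - 0.5) * px. A pixel is foreground iff its
## center lies inside the analytic shape.

field_dims <- function(field_um, pixel_size) {
  c(ny = max(1L, round(field_um[2] / pixel_size)),
    nx = max(1L, round(field_um[1] / pixel_size)))
}

pixel_centers <- function(rows, cols, pixel_size) {
  list(x = (cols - 0.5) * pixel_size, y = (rows - 0.5) * pixel_size)
}

## Add pixels inside an ellipse (center/axes in um, orientation radians) to a
## logical matrix. Returns the updated matrix.
rasterize_ellipse <- function(mask, cx, cy, a, b, theta, pixel_size) {
  d <- dim(mask)
  rmax <- a
  r0 <- max(1L, floor((cy - rmax) / pixel_size))
  r1 <- min(d[1], ceiling((cy + rmax) / pixel_size) + 1L)
  c0 <- max(1L, floor((cx - rmax) / pixel_size))
  c1 <- min(d[2], ceiling((cx + rmax) / pixel_size) + 1L)
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  xc <- (rep(cols, each = length(rows)) - 0.5) * pixel_size - cx
  yc <- (rep(rows, times = length(cols)) - 0.5) * pixel_size - cy
  u <- cos(theta) * xc + sin(theta) * yc
  v <- -sin(theta) * xc + cos(theta) * yc
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- mask[rows, cols]
  sub[inside] <- TRUE
  mask[rows, cols] <- sub
  mask
}

## Distance from pixel centers in a window to a segment p0-p1 (um coords);
## marks pixels with distance <= radius.
rasterize_tube_segment <- function(mask, p0, p1, radius, pixel_size) {
  d <- dim(mask)
  lo <- pmin(p0, p1) - radius
  hi <- pmax(p0, p1) + radius
  r0 <- max(1L, floor(lo[2] / pixel_size))
  r1 <- min(d[1], ceiling(hi[2] / pixel_size) + 1L)
  c0 <- max(1L, floor(lo[1] / pixel_size))
  c1 <- min(d[2], ceiling(hi[1] / pixel_size) + 1L)
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  xc <- (rep(cols, each = length(rows)) - 0.5) * pixel_size
  yc <- (rep(rows, times = length(cols)) - 0.5) * pixel_size
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx^2 + vy^2
  if (len2 == 0) {
    dist2 <- (xc - p0[1])^2 + (yc - p0[2])^2
  } else {
    t <- pmin(pmax(((xc - p0[1]) * vx + (yc - p0[2]) * vy) / len2, 0), 1)
    dist2 <- (xc - (p0[1] + t * vx))^2 + (yc - (p0[2] + t * vy))^2
  }
  inside <- dist2 <= radius^2
  sub <- mask[rows, cols]
  sub[inside] <- TRUE
  mask[rows, cols] <- sub
  mask
}

rasterize_tube <- function(mask, poly, radius, pixel_size) {
  for (i in seq_len(nrow(poly) - 1L))
    mask <- rasterize_tube_segment(mask, poly[i, ], poly[i + 1L, ],
                                   radius, pixel_size)
  mask
}

## Add an isotropic Gaussian intensity bump at (cx, cy) um. The bump is
## normalized so that its maximum on the pixel grid equals `amp`: planted
## punctum amplitudes are peak intensities as measurable in the image.
add_gaussian_spot <- function(img, cx, cy, amp, sigma, pixel_size) {
  d <- dim(img)
  ext <- 4 * sigma
  r0 <- max(1L, floor((cy - ext) / pixel_size))
  r1 <- min(d[1], ceiling((cy + ext) / pixel_size) + 1L)
  c0 <- max(1L, floor((cx - ext) / pixel_size))
  c1 <- min(d[2], ceiling((cx + ext) / pixel_size) + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  xc <- (rep(cols, each = length(rows)) - 0.5) * pixel_size - cx
  yc <- (rep(rows, times = length(cols)) - 0.5) * pixel_size - cy
  bump <- exp(-(xc^2 + yc^2) / (2 * sigma^2))
  mx <- max(bump)
  if (mx > 0) img[rows, cols] <- img[rows, cols] + amp * bump / mx
  img
}

polyline_arclength <- function(poly) {
  if (nrow(poly) < 2L) return(0)
  sum(sqrt(rowSums((poly[-1L, , drop = FALSE] -
                      poly[-nrow(poly), , drop = FALSE])^2)))
}

## Point at arclength s along a polyline (um coords); also the local unit
## tangent there.
polyline_point <- function(poly, s) {
  seg <- sqrt(rowSums((poly[-1L, , drop = FALSE] -
                         poly[-nrow(poly), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  s <- min(max(s, 0), cs[length(cs)])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  t <- if (seg[i] > 0) (s - cs[i]) / seg[i] else 0
  p <- poly[i, ] + t * (poly[i + 1L, ] - poly[i, ])
  tang <- poly[i + 1L, ] - poly[i, ]
  nt <- sqrt(sum(tang^2))
  list(point = p, tangent = if (nt > 0) tang / nt else c(1, 0))
}

## Densely resample a polyline at ~step spacing (for separation checks).
polyline_samples <- function(poly, step = 0.1) {
  L <- polyline_arclength(poly)
  if (L == 0) return(poly[1, , drop = FALSE])
  s <- seq(0, L, by = step)
  t(vapply(s, function(si) polyline_point(poly, si)$point, numeric(2)))
}

## Random smooth polyline inside a field: fixed step with angular jitter and
## soft steering back toward the field center near the margin.
random_polyline <- function(start, theta0, length_um, field_um,
                            step_um = 0.25, wiggle = 0.15, margin = 0.5) {
  n <- max(2L, ceiling(length_um / step_um) + 1L)
  pts <- matrix(0, n, 2)
  pts[1, ] <- start
  theta <- theta0
  ctr <- field_um / 2
  for (i in 2:n) {
    p <- pts[i - 1L, ]
    near <- p[1] < margin || p[2] < margin ||
      p[1] > field_um[1] - margin || p[2] > field_um[2] - margin
    if (near) {
      to_ctr <- atan2(ctr[2] - p[2], ctr[1] - p[1])
      dth <- atan2(sin(to_ctr - theta), cos(to_ctr - theta))
      theta <- theta + sign(dth) * min(abs(dth), 0.5)
    }
    theta <- theta + stats::rnorm(1, 0, wiggle)
    pts[i, ] <- p + step_um * c(cos(theta), sin(theta))
  }
  # trim to the requested arclength exactly
  seg <- step_um * (n - 1L)
  if (seg > length_um && n > 2L) {
    excess <- seg - length_um
    dirv <- pts[n, ] - pts[n - 1L, ]
    pts[n, ] <- pts[n, ] - dirv / sqrt(sum(dirv^2)) * excess
  }
  pts
}

min_dist_to_points <- function(pts, ref) {
  if (is.null(ref) || nrow(ref) == 0L) return(Inf)
  d2 <- outer(pts[, 1], ref[, 1], "-")^2 + outer(pts[, 2], ref[, 2], "-")^2
  sqrt(min(d2))
}
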