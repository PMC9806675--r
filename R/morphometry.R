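#' @name morphometry
#' @title Per-object shape metrics for vesicle morphology
#'
#' @description
#' Two shape readouts characterize endosome morphology:
#'
#' * **roundness**: the normalized ratio of the radius of the largest circle
#'   inscribed in the object to the radius of the smallest circle enclosing
#'   it, expressed as a percentage (100 for a disk, 50 for a 2:1 ellipse);
#' * **elongation**: the ratio of the first to the second diameter of the
#'   ellipse with the same normalized second central moments as the object
#'   (>= 1, with 1 for a non-elongated object).
#'
#' All circle computations use pixel-center arithmetic: a pixel's position is
#' its center, and distances are measured center-to-center, so results are
#' reproducible bit-for-bit against brute-force enumeration.
NULL

## Fill interior holes: background components (4-connected) not touching the
## array border are holes. An annulus otherwise gets a spuriously tiny
## inscribed circle.
fill_holes <- function(region) {
  bg <- !region
  lab <- label(bg, connectivity = 4L)
  n <- attr(lab, "n")
  if (n == 0L) return(region)
  d <- dim(region)
  border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
  border <- border[border > 0L]
  holes <- setdiff(seq_len(n), border)
  if (length(holes)) region[lab %in% holes] <- TRUE
  region
}

#' Largest inscribed circle radius of a region
#'
#' Radius of the largest circle that fits inside the object: the maximum,
#' over foreground pixel centers, of the distance to the nearest background
#' pixel center. Interior holes are filled first (see the vignette).
#'
#' @param region logical matrix holding a single connected object.
#' @param pixel_size micrometers per pixel.
#' @param fill fill interior holes before measuring (default TRUE).
#' @return radius in micrometers.
#' @export
inscribed_radius <- function(region, pixel_size = 1, fill = TRUE) {
  stopifnot(is.matrix(region))
  if (!any(region)) stopf("inscribed_radius: empty region")
  if (fill) region <- fill_holes(region)
  d <- dim(region)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- region
  dist <- edt_distance(!pad, spacing = c(1, 1))
  max(dist[pad]) * pixel_size
}

#' Minimum enclosing circle radius of a region
#'
#' Radius of the smallest circle containing every foreground pixel center,
#' computed by Welzl's randomized algorithm on the convex hull of the pixel
#' centers (the hull determines the enclosing circle).
#'
#' @inheritParams inscribed_radius
#' @return radius in micrometers (0 for a single-pixel region).
#' @export
circumscribed_radius <- function(region, pixel_size = 1) {
  stopifnot(is.matrix(region))
  idx <- which(region)
  if (length(idx) == 0L) stopf("circumscribed_radius: empty region")
  rc <- arrayInd(idx, dim(region))
  pts <- cbind(rc[, 2] - 0.5, rc[, 1] - 0.5)  # (x, y) pixel centers
  min_enclosing_circle(pts)$radius * pixel_size
}

## Minimum enclosing circle of a 2-column point matrix: convex hull, then
## Welzl's move-to-front algorithm. Returns list(center, radius).
min_enclosing_circle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1L) return(list(center = pts[1, ], radius = 0))
  if (n > 3L) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    if (length(h) >= 2L) pts <- pts[h, , drop = FALSE]
    n <- nrow(pts)
  }
  circ2 <- function(a, b) {
    ctr <- (a + b) / 2
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }
  circ3 <- function(a, b, c) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
    dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(dd) < 1e-12) return(NULL)  # collinear
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / dd
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }
  inside <- function(circ, p, eps = 1e-9)
    sqrt(sum((p - circ$center)^2)) <= circ$radius + eps
  trivial <- function(R) {
    if (nrow(R) == 0L) return(list(center = c(0, 0), radius = -1))
    if (nrow(R) == 1L) return(list(center = R[1, ], radius = 0))
    if (nrow(R) == 2L) return(circ2(R[1, ], R[2, ]))
    # 3 boundary points: try pairs first (handles obtuse/collinear), else circum
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      cc <- circ2(R[pair[1], ], R[pair[2], ])
      other <- setdiff(1:3, pair)
      if (inside(cc, R[other, ])) return(cc)
    }
    circ3(R[1, ], R[2, ], R[3, ])
  }
  welzl <- function(P, R) {
    if (nrow(P) == 0L || nrow(R) == 3L) return(trivial(R))
    p <- P[nrow(P), ]
    cc <- welzl(P[-nrow(P), , drop = FALSE], R)
    if (!is.null(cc) && cc$radius >= 0 && inside(cc, p)) return(cc)
    welzl(P[-nrow(P), , drop = FALSE], rbind(R, p))
  }
  # fixed interleaved order: deterministic (no RNG side effects) and avoids
  # the adversarial sorted-hull case; n is small (hull vertices only)
  ord <- as.vector(rbind(seq_len(n), rev(seq_len(n))))[seq_len(n)]
  ord <- unique(ord)
  welzl(pts[ord, , drop = FALSE], pts[0, , drop = FALSE])
}

#' Roundness of a region (percent)
#'
#' `100 * inscribed_radius / circumscribed_radius`: 100 for a disk, about 50
#' for a 2:1 ellipse, about 70.7 for a square. Single-pixel regions are
#' defined to have roundness 100 (point limit).
#'
#' @inheritParams inscribed_radius
#' @return roundness percentage in `(0, 100]` up to rasterization tolerance.
#' @export
roundness <- function(region, pixel_size = 1) {
  if (sum(region) == 1L) return(100)
  ri <- inscribed_radius(region, pixel_size)
  rc <- circumscribed_radius(region, pixel_size)
  100 * ri / rc
}

#' Elongation of a region
#'
#' Ratio `d1 / d2 >= 1` of the axis diameters of the ellipse with the same
#' normalized second central moments as the region. Pixels are treated as
#' unit squares (a 1/12 variance term is added per axis), so an `L x W`
#' rectangle yields exactly `L / W`, and a 1-px-wide run of `L` collinear
#' pixels yields `L` rather than a degenerate infinity. A non-elongated
#' object (disk) yields 1. Should the minor moment ever vanish numerically,
#' `Inf` is returned with attribute `degenerate = TRUE` and a warning.
#'
#' @param region logical matrix holding a single object.
#' @return elongation (>= 1), possibly `Inf` for collinear regions.
#' @export
elongation <- function(region) {
  stopifnot(is.matrix(region))
  idx <- which(region)
  if (length(idx) == 0L) stopf("elongation: empty region")
  if (length(idx) == 1L) return(1)
  rc <- arrayInd(idx, dim(region))
  x <- rc[, 2]; y <- rc[, 1]
  mx <- mean(x); my <- mean(y)
  # second central moments of the union of unit-square pixels
  mxx <- mean((x - mx)^2) + 1 / 12
  myy <- mean((y - my)^2) + 1 / 12
  mxy <- mean((x - mx) * (y - my))
  tr <- mxx + myy
  det <- mxx * myy - mxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l2 <= 1e-12) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    warnf("degenerate region (zero minor second moment): elongation = Inf")
    return(out)
  }
  sqrt(l1 / l2)
}

#' Measure morphometry of every labeled object
#'
#' One record per object: area, inscribed and enclosing circle radii,
#' roundness, elongation and centroid. A per-image summary (mean, median,
#' SD, n of roundness and elongation) is attached as attribute `summary`,
#' covering both common per-cell aggregations.
#'
#' @param labels integer label matrix from [label()].
#' @param pixel_size micrometers per pixel.
#' @return a `data.frame` with columns `label`, `area_um2`, `r_inscribed_um`,
#'   `r_circumscribed_um`, `roundness_pct`, `elongation`, `centroid_x_um`,
#'   `centroid_y_um`; attribute `summary`.
#' @export
measure_all <- function(labels, pixel_size = 1) {
  n <- attr(labels, "n") %||% max(labels)
  rows <- vector("list", n)
  for (id in seq_len(n)) {
    idx <- which(labels == id)
    rc <- arrayInd(idx, dim(labels))
    # crop to the bounding box (plus a background ring): metrics only see the
    # object itself, so this is exact and much faster on sparse fields
    r0 <- min(rc[, 1]); r1 <- max(rc[, 1]); c0 <- min(rc[, 2]); c1 <- max(rc[, 2])
    reg <- matrix(FALSE, r1 - r0 + 3L, c1 - c0 + 3L)
    reg[cbind(rc[, 1] - r0 + 2L, rc[, 2] - c0 + 2L)] <- TRUE
    ri <- if (length(idx) == 1L) pixel_size else inscribed_radius(reg, pixel_size)
    rcc <- circumscribed_radius(reg, pixel_size)
    rows[[id]] <- data.frame(
      label = id,
      area_um2 = length(idx) * pixel_size^2,
      r_inscribed_um = ri,
      r_circumscribed_um = rcc,
      roundness_pct = if (length(idx) == 1L) 100 else 100 * ri / rcc,
      elongation = as.numeric(elongation(reg)),
      centroid_x_um = (mean(rc[, 2]) - 0.5) * pixel_size,
      centroid_y_um = (mean(rc[, 1]) - 0.5) * pixel_size)
  }
  out <- if (n > 0) do.call(rbind, rows) else
    data.frame(label = integer(0), area_um2 = numeric(0),
               r_inscribed_um = numeric(0), r_circumscribed_um = numeric(0),
               roundness_pct = numeric(0), elongation = numeric(0),
               centroid_x_um = numeric(0), centroid_y_um = numeric(0))
  fin <- is.finite(out$elongation)
  attr(out, "summary") <- data.frame(
    metric = c("roundness_pct", "elongation"),
    mean = c(mean(out$roundness_pct), mean(out$elongation[fin])),
    median = c(stats::median(out$roundness_pct), stats::median(out$elongation[fin])),
    sd = c(stats::sd(out$roundness_pct), stats::sd(out$elongation[fin])),
    n = c(nrow(out), sum(fin)))
  out
}
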