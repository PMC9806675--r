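# Shape rasterizers and brute-force geometric oracles used across tests.
# Oracles are deliberately naive (pixel-center arithmetic, full enumeration)
# and independent of the package's implementations.

raster_disk <- function(radius_px, size = NULL, center = NULL) {
  if (is.null(size)) size <- ceiling(2 * radius_px) + 6L
  if (is.null(center)) center <- c(size, size) / 2
  outer(seq_len(size), seq_len(size), function(r, c)
    ((r - 0.5) - center[1])^2 + ((c - 0.5) - center[2])^2 <= radius_px^2)
}

raster_ellipse_px <- function(a_px, b_px, theta = 0, size = NULL) {
  if (is.null(size)) size <- ceiling(2 * a_px) + 8L
  ctr <- size / 2
  outer(seq_len(size), seq_len(size), function(r, c) {
    x <- (c - 0.5) - ctr; y <- (r - 0.5) - ctr
    u <- cos(theta) * x + sin(theta) * y
    v <- -sin(theta) * x + cos(theta) * y
    (u / a_px)^2 + (v / b_px)^2 <= 1
  })
}

# Connected random blob grown by attaching random boundary pixels.
rand_blob <- function(n_px, size = 28L) {
  m <- matrix(FALSE, size, size)
  cur <- matrix(c(size %/% 2, size %/% 2), 1)
  m[cur] <- TRUE
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  frontier <- cur
  while (sum(m) < n_px && nrow(frontier) > 0) {
    i <- sample.int(nrow(frontier), 1)
    p <- frontier[i, ]
    q <- p + offs[sample.int(4, 1), ]
    if (any(q < 2) || any(q > size - 1)) next
    if (!m[q[1], q[2]]) {
      m[q[1], q[2]] <- TRUE
      frontier <- rbind(frontier, q)
    }
  }
  m
}

# Brute-force largest inscribed radius: max over foreground pixel centers of
# the min distance to any background pixel center (on a 1-px padded grid).
bf_inscribed <- function(region) {
  d <- dim(region)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- region
  fg <- which(pad, arr.ind = TRUE)
  bg <- which(!pad, arr.ind = TRUE)
  best <- 0
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2
    best <- max(best, min(d2))
  }
  sqrt(best)
}

# Brute-force minimum enclosing circle radius: enumerate all supporting
# pairs and triples of convex-hull vertices (the MEC is determined by hull
# points), validate against every foreground point, take the smallest valid.
bf_mec_radius <- function(region) {
  rc <- which(region, arr.ind = TRUE)
  pts <- cbind(rc[, 2] - 0.5, rc[, 1] - 0.5)
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1L) return(0)
  h <- if (n > 3) pts[grDevices::chull(pts), , drop = FALSE] else pts
  eps <- 1e-9
  valid_r <- function(ctr, r) all(sqrt((pts[, 1] - ctr[1])^2 +
                                         (pts[, 2] - ctr[2])^2) <= r + eps)
  best <- Inf
  nh <- nrow(h)
  for (i in seq_len(nh - 1)) for (j in (i + 1):nh) {
    ctr <- (h[i, ] + h[j, ]) / 2
    r <- sqrt(sum((h[i, ] - ctr)^2))
    if (r < best && valid_r(ctr, r)) best <- r
  }
  if (nh >= 3) {
    for (i in seq_len(nh - 2)) for (j in (i + 1):(nh - 1)) for (k in (j + 1):nh) {
      a <- h[i, ]; b <- h[j, ]; c <- h[k, ]
      dd <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
      if (abs(dd) < 1e-12) next
      ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
               (sum(c^2)) * (a[2] - b[2])) / dd
      uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
               (sum(c^2)) * (b[1] - a[1])) / dd
      r <- sqrt(sum((a - c(ux, uy))^2))
      if (r < best && valid_r(c(ux, uy), r)) best <- r
    }
  }
  best
}

# Brute-force anisotropic shortest distance between a voxel object and a mask.
bf_shortest_distance <- function(obj_idx, maskB, spacing) {
  d <- dim(maskB)
  a <- arrayInd(obj_idx, d)
  b <- which(maskB, arr.ind = TRUE)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (spacing[1] * (b[, 1] - a[i, 1]))^2 +
      (spacing[2] * (b[, 2] - a[i, 2]))^2 +
      (spacing[3] * (b[, 3] - a[i, 3]))^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}
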