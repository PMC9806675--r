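## 3D voxel helpers: coordinates are (x, y, z) micrometers with voxel centers
## at ((c-0.5)*px, (r-0.5)*px, (s-0.5)*zs).

mark_sphere_3d <- function(mask, ctr, radius, px, zs) {
  d <- dim(mask)
  r0 <- max(1L, floor((ctr[2] - radius) / px))
  r1 <- min(d[1], ceiling((ctr[2] + radius) / px) + 1L)
  c0 <- max(1L, floor((ctr[1] - radius) / px))
  c1 <- min(d[2], ceiling((ctr[1] + radius) / px) + 1L)
  s0 <- max(1L, floor((ctr[3] - radius) / zs))
  s1 <- min(d[3], ceiling((ctr[3] + radius) / zs) + 1L)
  if (r0 > r1 || c0 > c1 || s0 > s1) return(mask)
  rows <- r0:r1; cols <- c0:c1; slcs <- s0:s1
  gy <- (rows - 0.5) * px - ctr[2]
  gx <- (cols - 0.5) * px - ctr[1]
  gz <- (slcs - 0.5) * zs - ctr[3]
  dist2 <- outer(outer(gy^2, gx^2, "+"), gz^2, "+")
  sub <- mask[rows, cols, slcs, drop = FALSE]
  sub[dist2 <= radius^2] <- TRUE
  mask[rows, cols, slcs] <- sub
  mask
}

mark_tube_3d <- function(mask, p0, p1, radius, px, zs) {
  L <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(L / (0.4 * min(px, zs))))
  for (t in seq(0, 1, length.out = n))
    mask <- mark_sphere_3d(mask, p0 + t * (p1 - p0), radius, px, zs)
  mask
}

#' Generate a synthetic 3D ER/marker/endosome scene
#'
#' Emulates a 3-channel confocal z-stack: an ER-like connected tubular
#' meshwork (`ER` channel), marker puncta attached to the ER surface
#' (`DFCP1` role), and endosomal objects (`SNX1` role) of which a fraction
#' `attach_fraction` is planted in contact with a marker-bearing ER locus
#' (voxel overlap, true shortest distance 0) while the remainder is planted
#' at a controlled gap distance from the ER. Anisotropic voxel spacing
#' follows confocal acquisition practice (default 0.07 um laterally, 0.08 um
#' axially).
#'
#' @param er_density target ER volume fraction in `(0, 1)`.
#' @param n_marker number of marker puncta on the ER.
#' @param n_endosome number of endosome objects.
#' @param gap_dist `c(mean, sd)` of the planted ER gap for non-attached
#'   endosomes (um).
#' @param attach_fraction fraction in `[0, 1]` of endosomes planted in
#'   contact with a marker-bearing ER locus.
#' @param field_um lateral field size `c(width, height)` um.
#' @param depth_um axial depth in um.
#' @param voxel `c(xy, z)` voxel size in um.
#' @param er_radius_um,marker_radius_um,endo_radius_um object radii (um).
#' @param amplitude per-channel peak intensity.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap.
#' @return list with `image` (3D [calibrated_image], channels `ER`, `DFCP1`,
#'   `SNX1`) and `truth` (planted distances and supports).
#' @export
make_er_scene_3d <- function(er_density = 0.04, n_marker = 12,
                             n_endosome = 16, gap_dist = c(0.8, 0.1),
                             attach_fraction = 0.5,
                             field_um = c(7, 7), depth_um = 1.6,
                             voxel = c(0.07, 0.08),
                             er_radius_um = 0.1, marker_radius_um = 0.12,
                             endo_radius_um = 0.18,
                             amplitude = 150, noise = noise_model(),
                             seed = 1, max_tries = 1000) {
  stopifnot(er_density > 0, er_density < 1, n_marker >= 0, n_endosome >= 0,
            attach_fraction >= 0, attach_fraction <= 1)
  px <- voxel[1]; zs <- voxel[2]
  with_seed(derive_seed(seed, "er_scene_3d"), {
    d2 <- field_dims(field_um, px)
    nz <- max(3L, round(depth_um / zs))
    dims <- c(d2["ny"], d2["nx"], nz)
    ext <- c(field_um[1], field_um[2], nz * zs)

    # connected meshwork: each new segment starts on the existing structure
    er <- array(FALSE, dims)
    ctr0 <- c(ext[1] / 2, ext[2] / 2, ext[3] / 2)
    anchors <- matrix(ctr0, 1, 3)
    guard <- 0
    while (mean(er) < er_density && guard < 10 * max_tries) {
      guard <- guard + 1
      a <- anchors[sample.int(nrow(anchors), 1), ]
      phi <- stats::runif(1, 0, 2 * pi)
      cz <- stats::runif(1, -0.35, 0.35)  # mostly lateral, ER sheets are flat-ish
      dir3 <- c(cos(phi) * sqrt(1 - cz^2), sin(phi) * sqrt(1 - cz^2), cz)
      L <- stats::runif(1, 0.6, 1.8)
      b <- a + L * dir3
      b <- pmin(pmax(b, c(0.4, 0.4, 0.15)), ext - c(0.4, 0.4, 0.15))
      er <- mark_tube_3d(er, a, b, er_radius_um, px, zs)
      anchors <- rbind(anchors, b, (a + b) / 2)
    }

    er_idx <- which(er)
    er_coord <- arrayInd(er_idx, dims)
    er_xyz <- cbind((er_coord[, 2] - 0.5) * px, (er_coord[, 1] - 0.5) * px,
                    (er_coord[, 3] - 0.5) * zs)

    # markers on ER voxels, mutually separated (wide enough that endosomes
    # attached to neighboring markers stay disjoint)
    marker <- array(FALSE, dims)
    marker_ctr <- matrix(numeric(0), 0, 3)
    for (m in seq_len(n_marker)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- er_xyz[sample.int(nrow(er_xyz), 1), ]
        if (nrow(marker_ctr) == 0 ||
            min(sqrt(rowSums(sweep(marker_ctr, 2, cand)^2))) > 0.7) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stopf("infeasible packing: marker %d after %d tries", m, max_tries)
      marker_ctr <- rbind(marker_ctr, cand)
      marker <- mark_sphere_3d(marker, cand, marker_radius_um, px, zs)
    }

    # endosomes: attached (overlap a marker locus) or at a planted ER gap
    edt_er <- edt_distance(er, spacing = c(px, px, zs))
    n_attach <- round(attach_fraction * n_endosome)
    if (n_attach > n_marker)
      stopf("attached endosomes (%d) cannot exceed markers (%d): each needs its own marker locus",
            n_attach, n_marker)
    attach_marker <- if (n_attach > 0) sample.int(n_marker, n_attach) else integer(0)
    endo <- array(FALSE, dims)
    endo_ctr <- matrix(numeric(0), 0, 3)
    endo_df <- NULL
    # candidate centers for gap placement: sample voxels whose distance to
    # the ER is near gap + endosome radius (the iso-distance shell), then
    # verify the realized surface distance; far more robust than casting
    # random directions from ER voxels
    for (e in seq_len(n_endosome)) {
      attached <- e <= n_attach
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        if (attached) {
          mc <- marker_ctr[attach_marker[e], ]
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- mc + 0.5 * endo_radius_um * u
          gap <- 0
        } else {
          gap <- max(0.05, stats::rnorm(1, gap_dist[1], gap_dist[2]))
          shell <- which(abs(edt_er - (gap + endo_radius_um)) < 0.08)
          if (!length(shell))
            stopf("no voxels at the requested gap distance %.2f um from the ER", gap)
          ci <- arrayInd(shell[sample.int(length(shell), 1)], dims)
          cand <- c((ci[2] - 0.5) * px, (ci[1] - 0.5) * px, (ci[3] - 0.5) * zs)
        }
        if (any(cand < c(0.3, 0.3, 0.2)) || any(cand > ext - c(0.3, 0.3, 0.2)))
          next
        if (nrow(endo_ctr) > 0 &&
            min(sqrt(rowSums(sweep(endo_ctr, 2, cand)^2))) <
              2 * endo_radius_um + 0.15)  # disjoint after rasterization
          next
        probe <- array(FALSE, dims)
        probe <- mark_sphere_3d(probe, cand, endo_radius_um, px, zs)
        if (!any(probe)) next
        dmeas <- min(edt_er[probe])
        if (attached) {
          if (dmeas > 0) next  # must overlap the ER at contact range 0
        } else {
          if (abs(dmeas - gap) > 0.1) next  # grid quantization guard
        }
        ok <- TRUE
        break
      }
      if (!ok) stopf("infeasible packing: endosome %d after %d tries", e, max_tries)
      endo <- endo | probe
      endo_ctr <- rbind(endo_ctr, cand)
      endo_df <- rbind(endo_df, data.frame(
        id = e, x_um = cand[1], y_um = cand[2], z_um = cand[3],
        radius_um = endo_radius_um, attached = attached,
        planted_gap_um = gap, d_er_um = dmeas))
    }
    edt_marker <- if (any(marker)) edt_distance(marker, spacing = c(px, px, zs)) else
      array(Inf, dims)
    if (!is.null(endo_df)) {
      endo_df$d_marker_um <- vapply(seq_len(nrow(endo_df)), function(e) {
        probe <- array(FALSE, dims)
        probe <- mark_sphere_3d(probe, as.numeric(endo_df[e, c("x_um", "y_um", "z_um")]),
                                endo_radius_um, px, zs)
        min(edt_marker[probe])
      }, numeric(1))
    }

    mk_ch <- function(support) apply_noise(amplitude * support, noise, px)
    img <- calibrated_image(
      array(c(mk_ch(er), mk_ch(marker), mk_ch(endo)), c(dims, 3L)),
      c("ER", "DFCP1", "SNX1"), px, z_step = zs)
    truth <- structure(list(
      type = "er3d", pixel_size = px, z_step = zs, field_um = field_um,
      depth_um = nz * zs, attach_fraction = attach_fraction,
      gap_dist = gap_dist,
      endosomes = endo_df,
      marker_centers = marker_ctr,
      masks = list(ER = er, DFCP1 = marker, SNX1 = endo),
      roi_area_um2 = prod(field_um)), class = "scene_truth")
    list(image = img, truth = truth)
  })
}
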