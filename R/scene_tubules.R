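#' Generate a synthetic tubule network scene with planted puncta
#'
#' Emulates a field of endosomal tubules as smooth random polylines of
#' constant tube radius, with a controlled number of side branches (each
#' branch node is a planted 3-way junction), plus two punctate channels
#' along the tubules: a reference channel (`LC3` role) of Gaussian puncta at
#' planted arclength positions and a target channel (`SNX2` role) that has a
#' uniform baseline along the tubule and puncta that colocalize with
#' reference puncta with probability `rho`, carrying amplitude
#' `baseline + delta` at colocalized sites.
#'
#' The ground truth records per-tubule planted arclengths (main axis, per
#' branch, and component totals), branch-node coordinates, every punctum,
#' `delta`, the noiseless tubule support mask, and the planted polylines in
#' both micrometer and pixel coordinates (for profile sampling).
#'
#' @param n_tubules number of tubules.
#' @param branch_count total number of side branches planted across tubules.
#' @param length_dist `c(mean, sd)` of main-axis tubule length (um).
#' @param puncta_model list with `n_ref` (reference puncta per tubule),
#'   `n_target` (target puncta per tubule), `delta` (target punctum peak
#'   above baseline, intensity units) and `rho` (colocalization probability
#'   in `[0, 1]`).
#' @param tube_radius_um tubule radius in micrometers.
#' @param branch_length_um `c(min, max)` branch arm length (um).
#' @param field_um field size `c(width, height)` in micrometers.
#' @param amplitude tubule backbone intensity (channel `SNX1`).
#' @param baseline target-channel baseline intensity along the tubule.
#' @param ref_amp mean reference punctum peak intensity.
#' @param punctum_sigma_um Gaussian punctum sigma (um).
#' @param pixel_size micrometers per pixel.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap.
#' @return list with `image` (channels `SNX1`, `LC3`, `SNX2`) and `truth`.
#' @export
make_tubule_scene <- function(n_tubules = 6, branch_count = 3,
                              length_dist = c(10, 2),
                              puncta_model = list(n_ref = 3, n_target = 3,
                                                  delta = 60, rho = 1),
                              tube_radius_um = 0.12,
                              branch_length_um = c(1.8, 3),
                              field_um = c(14, 14), amplitude = 150,
                              baseline = 40, ref_amp = 100,
                              punctum_sigma_um = 0.15, pixel_size = 0.07,
                              noise = noise_model(), seed = 1,
                              max_tries = 1000) {
  stopifnot(n_tubules >= 0, branch_count >= 0,
            puncta_model$rho >= 0, puncta_model$rho <= 1)
  with_seed(derive_seed(seed, "tubule_scene"), {
    d <- field_dims(field_um, pixel_size)
    sep <- 4 * tube_radius_um + 0.35  # min clearance between distinct tubules
    polys <- list()
    samples_all <- NULL
    lengths <- numeric(0)
    for (i in seq_len(n_tubules)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        L <- max(2, stats::rnorm(1, length_dist[1], length_dist[2]))
        start <- c(stats::runif(1, 1, field_um[1] - 1),
                   stats::runif(1, 1, field_um[2] - 1))
        theta0 <- stats::runif(1, 0, 2 * pi)
        poly <- random_polyline(start, theta0, L, field_um)
        smp <- polyline_samples(poly, 0.1)
        if (any(smp[, 1] < 0.3) || any(smp[, 2] < 0.3) ||
            any(smp[, 1] > field_um[1] - 0.3) ||
            any(smp[, 2] > field_um[2] - 0.3)) next
        # self-separation: no two samples far apart in arclength may be close
        ns <- nrow(smp)
        self_ok <- TRUE
        if (ns > 20) {
          for (k in seq(1, ns - 16, by = 4)) {
            far <- smp[(k + 15):ns, , drop = FALSE]
            dmin <- sqrt(min((far[, 1] - smp[k, 1])^2 + (far[, 2] - smp[k, 2])^2))
            if (dmin < sep) { self_ok <- FALSE; break }
          }
        }
        if (!self_ok) next
        if (min_dist_to_points(smp, samples_all) > sep) { ok <- TRUE; break }
      }
      if (!ok) stopf("infeasible packing: tubule %d after %d tries", i, max_tries)
      polys[[i]] <- poly
      lengths[i] <- polyline_arclength(poly)
      samples_all <- rbind(samples_all, polyline_samples(poly, 0.1))
    }

    # distribute branches over tubules
    branches <- list()
    branch_df <- NULL
    if (branch_count > 0 && n_tubules > 0) {
      host <- sort(sample(rep_len(seq_len(n_tubules), max(branch_count, n_tubules))[
        seq_len(branch_count)]))
      for (bi in seq_len(branch_count)) {
        tid <- host[bi]
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          s_at <- stats::runif(1, 0.25, 0.75) * lengths[tid]
          # keep branch attach points well separated on the same tubule
          if (!is.null(branch_df)) {
            same <- branch_df[branch_df$tubule == tid, , drop = FALSE]
            if (nrow(same) > 0 && any(abs(same$s_um - s_at) < 1.2)) next
          }
          at <- polyline_point(polys[[tid]], s_at)
          side <- sample(c(-1, 1), 1)
          ang <- atan2(at$tangent[2], at$tangent[1]) +
            side * stats::runif(1, pi / 2.6, pi / 1.7)
          Lb <- stats::runif(1, branch_length_um[1], branch_length_um[2])
          bp <- random_polyline(at$point, ang, Lb, field_um, wiggle = 0.08)
          smp <- polyline_samples(bp, 0.1)
          if (any(smp[, 1] < 0.3) || any(smp[, 2] < 0.3) ||
              any(smp[, 1] > field_um[1] - 0.3) ||
              any(smp[, 2] > field_um[2] - 0.3)) next
          # beyond the junction region, the arm must stay clear of all
          # tubules and branches (it necessarily touches its parent there)
          root_d <- apply(smp, 1, function(p) sqrt(sum((p - at$point)^2)))
          tail_smp <- smp[root_d > 1.0, , drop = FALSE]
          others <- samples_all
          for (ob in branches) others <- rbind(others, polyline_samples(ob$poly, 0.1))
          if (nrow(tail_smp) > 0 && min_dist_to_points(tail_smp, others) < 0.5)
            next
          ok <- TRUE
          break
        }
        if (!ok) stopf("infeasible packing: branch %d after %d tries", bi, max_tries)
        branches[[bi]] <- list(tubule = tid, poly = bp, length_um = polyline_arclength(bp),
                               attach = at$point, s_um = s_at)
        branch_df <- rbind(branch_df, data.frame(
          branch = bi, tubule = tid, s_um = s_at, length_um = polyline_arclength(bp),
          x_um = at$point[1], y_um = at$point[2]))
      }
    }

    # puncta: reference positions per tubule, then target positions
    n_ref <- puncta_model$n_ref %||% 3
    n_target <- puncta_model$n_target %||% n_ref
    delta <- puncta_model$delta %||% 60
    rho <- puncta_model$rho %||% 1
    puncta <- NULL
    for (tid in seq_len(n_tubules)) {
      L <- lengths[tid]
      ref_s <- numeric(0)
      guard <- 0
      while (length(ref_s) < n_ref && guard < max_tries) {
        guard <- guard + 1
        cand <- stats::runif(1, 0.12 * L, 0.88 * L)
        if (all(abs(ref_s - cand) > 0.6)) ref_s <- c(ref_s, cand)
      }
      ref_s <- sort(ref_s)
      for (k in seq_along(ref_s)) {
        p <- polyline_point(polys[[tid]], ref_s[k])$point
        puncta <- rbind(puncta, data.frame(
          tubule = tid, channel = "LC3", s_um = ref_s[k],
          x_um = p[1], y_um = p[2],
          amplitude = ref_amp * stats::runif(1, 0.8, 1.25),
          coloc = NA, ref_index = k))
      }
      for (k in seq_len(n_target)) {
        coloc <- stats::runif(1) < rho && k <= length(ref_s)
        # non-colocalized puncta fall uniformly, independent of the
        # reference positions (independence is what rho = 0 means)
        s_t <- if (coloc) ref_s[k] else stats::runif(1, 0.08 * L, 0.92 * L)
        p <- polyline_point(polys[[tid]], s_t)$point
        puncta <- rbind(puncta, data.frame(
          tubule = tid, channel = "SNX2", s_um = s_t,
          x_um = p[1], y_um = p[2], amplitude = delta,
          coloc = coloc, ref_index = if (coloc) k else NA))
      }
    }

    # rasterize support and intensity channels
    support <- matrix(FALSE, d["ny"], d["nx"])
    for (poly in polys) support <- rasterize_tube(support, poly, tube_radius_um, pixel_size)
    for (b in branches) support <- rasterize_tube(support, b$poly, tube_radius_um, pixel_size)
    ch_snx1 <- amplitude * support
    ch_lc3 <- matrix(0, d["ny"], d["nx"])
    ch_snx2 <- baseline * support
    if (!is.null(puncta)) for (j in seq_len(nrow(puncta))) {
      pj <- puncta[j, ]
      if (pj$channel == "LC3") {
        ch_lc3 <- add_gaussian_spot(ch_lc3, pj$x_um, pj$y_um, pj$amplitude,
                                    punctum_sigma_um, pixel_size)
      } else {
        ch_snx2 <- add_gaussian_spot(ch_snx2, pj$x_um, pj$y_um, pj$amplitude,
                                     punctum_sigma_um, pixel_size)
      }
    }
    img <- calibrated_image(
      array(c(apply_noise(ch_snx1, noise, pixel_size),
              apply_noise(ch_lc3, noise, pixel_size),
              apply_noise(ch_snx2, noise, pixel_size)),
            c(d["ny"], d["nx"], 3L)),
      c("SNX1", "LC3", "SNX2"), pixel_size)

    branch_per_tub <- if (is.null(branch_df)) integer(n_tubules) else
      tabulate(branch_df$tubule, nbins = n_tubules)
    branch_len <- if (is.null(branch_df)) numeric(n_tubules) else
      vapply(seq_len(n_tubules), function(t)
        sum(branch_df$length_um[branch_df$tubule == t]), numeric(1))
    tub_df <- if (n_tubules > 0) data.frame(
      id = seq_len(n_tubules), length_um = lengths,
      n_branches = branch_per_tub,
      total_length_um = lengths + branch_len) else
        data.frame(id = integer(0), length_um = numeric(0),
                   n_branches = integer(0), total_length_um = numeric(0))
    polylines_px <- lapply(polys, function(p) p / pixel_size)
    truth <- structure(list(
      type = "tubule", pixel_size = pixel_size, field_um = field_um,
      tubules = tub_df, branches = branch_df,
      n_branch_nodes = branch_count,
      puncta = puncta, delta = delta, rho = rho,
      polylines_um = polys, polylines_px = polylines_px,
      masks = list(SNX1 = support),
      roi_area_um2 = prod(field_um)), class = "scene_truth")
    list(image = img, truth = truth)
  })
}
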