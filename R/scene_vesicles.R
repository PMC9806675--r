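#' Generate a synthetic vesicle field with planted morphometry
#'
#' Emulates a 2D field of early endosomes: round vesicles (circles) and
#' elongated vesicles (ellipses with aspect ratio drawn from `aspect_range`),
#' placed without overlap by rejection sampling, rasterized by pixel-center
#' inclusion, blurred by the PSF and corrupted by Poisson + Gaussian camera
#' noise. Round vesicles appear in the `EEA1` channel only; elongated
#' vesicles carry signal in both `EEA1` and `SNX1`, so the two channel
#' supports have a known planted overlap.
#'
#' The ground truth records every object's planted roundness (`100 * b / a`)
#' and elongation (`a / b`), the noiseless per-channel support masks, and the
#' pairwise mask overlap fractions.
#'
#' @param n_round number of round vesicles.
#' @param n_elongated number of elongated vesicles.
#' @param aspect_range `c(min, max)` aspect ratio (a/b) for elongated
#'   vesicles; min must be >= 1.
#' @param field_um field size `c(width, height)` in micrometers.
#' @param radius_range_um semi-minor axis range in micrometers.
#' @param amplitude peak intensity of vesicle signal.
#' @param pixel_size micrometers per pixel.
#' @param noise a [noise_model()].
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   output.
#' @param max_tries rejection-sampling cap per object before an infeasible
#'   packing error.
#' @return a list with elements `image` (a [calibrated_image] with channels
#'   `EEA1`, `SNX1`) and `truth` (a `scene_truth` list).
#' @export
make_vesicle_scene <- function(n_round = 12, n_elongated = 8,
                               aspect_range = c(1.8, 3.5),
                               field_um = c(15, 15),
                               radius_range_um = c(0.25, 0.45),
                               amplitude = 150, pixel_size = 0.07,
                               noise = noise_model(), seed = 1,
                               max_tries = 1000) {
  stopifnot(n_round >= 0, n_elongated >= 0, aspect_range[1] >= 1)
  with_seed(derive_seed(seed, "vesicle_scene"), {
    d <- field_dims(field_um, pixel_size)
    n <- n_round + n_elongated
    specs <- NULL
    placed <- matrix(numeric(0), 0, 3)  # cx, cy, clearance radius
    for (i in seq_len(n)) {
      elong <- i > n_round
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        b <- stats::runif(1, radius_range_um[1], radius_range_um[2])
        asp <- if (elong) stats::runif(1, aspect_range[1], aspect_range[2]) else 1
        a <- b * asp
        theta <- stats::runif(1, 0, pi)
        margin <- a + 2 * pixel_size
        cx <- stats::runif(1, margin, field_um[1] - margin)
        cy <- stats::runif(1, margin, field_um[2] - margin)
        clear <- a + 0.15
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                placed[, 3] + clear)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stopf("infeasible packing: could not place object %d in %d tries",
                     i, max_tries)
      placed <- rbind(placed, c(cx, cy, clear))
      specs <- rbind(specs, data.frame(
        id = i, cx_um = cx, cy_um = cy, a_um = a, b_um = b, theta = theta,
        elongated = elong, roundness_pct = 100 * b / a, elongation = a / b))
    }
    mask_eea1 <- matrix(FALSE, d["ny"], d["nx"])
    mask_snx1 <- matrix(FALSE, d["ny"], d["nx"])
    if (n > 0) for (i in seq_len(n)) {
      s <- specs[i, ]
      mask_eea1 <- rasterize_ellipse(mask_eea1, s$cx_um, s$cy_um, s$a_um,
                                     s$b_um, s$theta, pixel_size)
      if (s$elongated)
        mask_snx1 <- rasterize_ellipse(mask_snx1, s$cx_um, s$cy_um, s$a_um,
                                       s$b_um, s$theta, pixel_size)
    }
    ch1 <- apply_noise(amplitude * mask_eea1, noise, pixel_size)
    ch2 <- apply_noise(amplitude * mask_snx1, noise, pixel_size)
    img <- calibrated_image(array(c(ch1, ch2), c(d["ny"], d["nx"], 2L)),
                            c("EEA1", "SNX1"), pixel_size)
    overlap <- function(a, b) if (sum(a) == 0) NA_real_ else 100 * sum(a & b) / sum(a)
    truth <- structure(list(
      type = "vesicle", pixel_size = pixel_size, field_um = field_um,
      vesicles = specs,
      masks = list(EEA1 = mask_eea1, SNX1 = mask_snx1),
      overlap_pct = c(EEA1_in_SNX1 = overlap(mask_eea1, mask_snx1),
                      SNX1_in_EEA1 = overlap(mask_snx1, mask_eea1)),
      roi_area_um2 = prod(field_um)), class = "scene_truth")
    list(image = img, truth = truth)
  })
}
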