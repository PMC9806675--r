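test_that("overlap fraction follows its defining formula", {
  A <- matrix(FALSE, 20, 20); A[1:10, 1:10] <- TRUE       # 100 px
  B <- matrix(FALSE, 20, 20); B[6:10, 1:5] <- TRUE        # 25 px inside A
  expect_equal(overlap_fraction(A, A), 100)
  expect_equal(overlap_fraction(A, !A), 0)
  expect_equal(overlap_fraction(A, B), 25)
  expect_false(isTRUE(all.equal(overlap_fraction(A, B), overlap_fraction(B, A))))
  expect_warning(z <- overlap_fraction(matrix(FALSE, 2, 2), matrix(TRUE, 2, 2)),
                 "empty")
  expect_equal(z, 0)
  expect_error(overlap_fraction(A, matrix(TRUE, 3, 3)), "shape")
})

test_that("merge percentage is symmetric with union and sum denominators", {
  A <- matrix(FALSE, 20, 20); A[1:10, 1:10] <- TRUE
  B <- matrix(FALSE, 20, 20); B[6:15, 1:10] <- TRUE       # |A|=|B|=100, inter=50
  expect_equal(as.numeric(merge_percentage(A, A)), 100)
  expect_equal(as.numeric(merge_percentage(A, !A)), 0)
  expect_equal(as.numeric(merge_percentage(A, B)), 100 * 50 / 150)
  expect_equal(as.numeric(merge_percentage(A, B, "sum")), 100 * 50 / 200)
  expect_equal(as.numeric(merge_percentage(A, B)),
               as.numeric(merge_percentage(B, A)))
  expect_equal(attr(merge_percentage(A, B), "denominator"), "union")
})

test_that("planted mask overlap is recovered to machine precision", {
  sc <- make_vesicle_scene(n_round = 6, n_elongated = 5,
                           noise = noise_none(), seed = 14)
  mS <- binarize(sc$image, "SNX1", method = "fixed", threshold = 1)
  mE <- binarize(sc$image, "EEA1", method = "fixed", threshold = 1)
  expect_equal(overlap_fraction(mS, mE),
               unname(sc$truth$overlap_pct["SNX1_in_EEA1"]), tolerance = 1e-12)
  expect_equal(overlap_fraction(mE, mS),
               unname(sc$truth$overlap_pct["EEA1_in_SNX1"]), tolerance = 1e-12)
})

test_that("puncta detection recovers planted spots on noiseless scenes", {
  sc <- make_tubule_scene(n_tubules = 4, branch_count = 0,
                          noise = noise_none(), seed = 7,
                          puncta_model = list(n_ref = 3, n_target = 3,
                                              delta = 60, rho = 1))
  sp <- detect_puncta(sc$image, "LC3", scale_um = 0.1)
  planted <- sc$truth$puncta[sc$truth$puncta$channel == "LC3", ]
  expect_equal(nrow(sp), nrow(planted))
  for (i in seq_len(nrow(sp))) {
    d <- min(sqrt((planted$x_um - sp$x_um[i])^2 + (planted$y_um - sp$y_um[i])^2))
    expect_lt(d / sc$image$pixel_size_xy, 1)  # within 1 px of a planted centroid
  }
  blank <- calibrated_image(matrix(0, 32, 32), "c", 0.07)
  expect_equal(nrow(detect_puncta(blank, "c")), 0L)
})

test_that("well-separated puncta are not merged", {
  img <- matrix(0, 64, 64)
  scale <- 0.15; px <- 0.07
  ctrs <- rbind(c(1.0, 1.0), c(1.0 + 3 * scale + 0.25, 1.0))
  for (i in 1:2)
    img <- endoquant:::add_gaussian_spot(img, ctrs[i, 1], ctrs[i, 2], 100,
                                         scale, px)
  ci <- calibrated_image(img, "c", px)
  sp <- detect_puncta(ci, "c", scale_um = scale)
  expect_equal(nrow(sp), 2L)
})

test_that("association percentage counts spots near the reference", {
  sc <- make_tubule_scene(n_tubules = 4, branch_count = 0,
                          noise = noise_none(), seed = 7)
  sp <- detect_puncta(sc$image, "LC3", scale_um = 0.1)
  mask <- binarize(sc$image, "SNX1", method = "fixed", threshold = 1)
  # planted puncta sit on tubules: all associated at radius 0
  expect_equal(puncta_association(sp, mask, radius_um = 0,
                                  pixel_size = sc$image$pixel_size_xy), 100)
  # no reference signal
  expect_equal(puncta_association(sp, matrix(FALSE, 10, 10) | FALSE,
                                  radius_um = 0, pixel_size = 0.07), 0)
  # no spots: undefined, flagged
  expect_warning(u <- puncta_association(endoquant:::empty_spots("c"), mask,
                                         radius_um = 0, pixel_size = 0.07),
                 "undefined")
  expect_true(is.na(u))
})

test_that("association is non-decreasing in the radius", {
  set.seed(3)
  spots <- data.frame(x_px = runif(10, 0, 50), y_px = runif(10, 0, 50))
  spots$x_um <- spots$x_px * 0.1; spots$y_um <- spots$y_px * 0.1
  spots$radius_um <- 0.1; spots$peak <- 1
  class(spots) <- c("spot_set", "data.frame")
  ref <- matrix(FALSE, 50, 50); ref[20:30, 20:30] <- TRUE
  vals <- vapply(c(0, 0.2, 0.5, 1, 2, 5), function(r)
    puncta_association(spots, ref, radius_um = r, pixel_size = 0.1), 0)
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[length(vals)], 100)
})
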