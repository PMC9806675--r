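test_that("analytic shapes give their textbook roundness and elongation", {
  disk <- raster_disk(15)
  expect_equal(as.numeric(elongation(disk)), 1, tolerance = 0.02)
  expect_equal(roundness(disk), 100, tolerance = 5)

  ell <- raster_ellipse_px(24, 12)
  expect_equal(roundness(ell), 50, tolerance = 2.5)
  expect_equal(as.numeric(elongation(ell)), 2, tolerance = 0.1)

  sq <- matrix(FALSE, 50, 50); sq[11:40, 11:40] <- TRUE
  expect_equal(roundness(sq), 100 / sqrt(2), tolerance = 0.05 * 100 / sqrt(2))

  # rectangles: moment ratio gives exactly L/W with the unit-square term
  for (LW in c(1, 2, 4)) {
    W <- 12L; L <- as.integer(W * LW)
    rect <- matrix(FALSE, W + 10L, L + 10L)
    rect[6:(5 + W), 6:(5 + L)] <- TRUE
    expect_equal(as.numeric(elongation(rect)), LW, tolerance = 1e-9)
  }
})

test_that("inscribed and enclosing radii match disk geometry", {
  disk <- raster_disk(10)
  expect_equal(inscribed_radius(disk, 0.1), 1.0, tolerance = 0.1)  # +- 1 px
  expect_equal(circumscribed_radius(disk), 10, tolerance = 1)
  # two pixels at distance d -> enclosing radius d/2
  m <- matrix(FALSE, 10, 10); m[3, 2] <- TRUE; m[3, 8] <- TRUE
  expect_equal(circumscribed_radius(m), 3)
  # 1-pixel region: inscribed = 1 px (adjacent background), enclosing = 0
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(inscribed_radius(one, 1), 1)
  expect_equal(circumscribed_radius(one), 0)
  expect_equal(roundness(one), 100)
  expect_equal(as.numeric(elongation(one)), 1)
  expect_error(inscribed_radius(matrix(FALSE, 3, 3)), "empty")
})

test_that("radii match brute-force oracles exactly on random blobs", {
  set.seed(101)
  for (rep in 1:15) {
    blob <- rand_blob(sample(5:200, 1))
    expect_equal(inscribed_radius(blob, 1, fill = FALSE), bf_inscribed(blob),
                 tolerance = 1e-9)
    expect_equal(circumscribed_radius(blob, 1), bf_mec_radius(blob),
                 tolerance = 1e-9)
  }
})

test_that("an annulus is measured on its filled outline", {
  ring <- raster_disk(12) & !raster_disk(6, size = 30)
  # with hole filling, the inscribed circle is that of the outer disk
  expect_equal(inscribed_radius(ring, 1), bf_inscribed(raster_disk(12)),
               tolerance = 1e-9)
})

test_that("a single-pixel-wide line behaves as an L x 1 rectangle", {
  # under the unit-square pixel convention the minor moment is 1/12, never
  # zero, so collinear pixel runs give finite elongation L (not infinity)
  line <- matrix(FALSE, 5, 20); line[3, 4:16] <- TRUE
  expect_equal(as.numeric(elongation(line)), 13, tolerance = 1e-9)
})

test_that("metrics are scale-invariant and rotation-robust", {
  e1 <- as.numeric(elongation(raster_ellipse_px(20, 10)))
  e2 <- as.numeric(elongation(raster_ellipse_px(40, 20)))
  expect_equal(e1, e2, tolerance = 0.02)
  r1 <- roundness(raster_disk(10)) ; r2 <- roundness(raster_disk(20))
  expect_equal(r1, r2, tolerance = 3)

  es <- vapply(seq(0, pi / 2, length.out = 7), function(th)
    as.numeric(elongation(raster_ellipse_px(24, 12, th))), 0)
  expect_lt((max(es) - min(es)) / mean(es), 0.03)
  rs <- vapply(seq(0, pi / 2, length.out = 7), function(th)
    roundness(raster_ellipse_px(24, 12, th)), 0)
  expect_lt((max(rs) - min(rs)) / mean(rs), 0.03)
})

test_that("roundness decreases and elongation increases with aspect ratio", {
  aspects <- c(1, 1.5, 2, 3, 4)
  rs <- vapply(aspects, function(a) roundness(raster_ellipse_px(12 * a, 12)), 0)
  es <- vapply(aspects, function(a)
    as.numeric(elongation(raster_ellipse_px(12 * a, 12))), 0)
  expect_true(all(diff(rs) < 0))
  expect_true(all(diff(es) > 0))
  expect_true(all(rs > 0 & rs <= 100 + 1))
  expect_true(all(es >= 1 - 1e-6))
})

test_that("measure_all recovers planted metrics on well-resolved vesicles", {
  sc <- make_vesicle_scene(n_round = 2, n_elongated = 3,
                           radius_range_um = c(0.8, 1.1),
                           field_um = c(25, 25),
                           noise = noise_none(), seed = 8)
  labs <- label(binarize(sc$image, "EEA1", method = "fixed", threshold = 1))
  m <- measure_all(labs, sc$image$pixel_size_xy)
  expect_equal(nrow(m), 5)
  tv <- sc$truth$vesicles
  for (i in seq_len(nrow(m))) {
    j <- which.min((tv$cx_um - m$centroid_x_um[i])^2 +
                     (tv$cy_um - m$centroid_y_um[i])^2)
    expect_equal(m$elongation[i], tv$elongation[j], tolerance = 0.05 * tv$elongation[j])
    expect_equal(m$roundness_pct[i], tv$roundness_pct[j],
                 tolerance = 0.05 * tv$roundness_pct[j])
    expect_lte(m$r_inscribed_um[i], m$r_circumscribed_um[i] + 1e-9)
  }
  expect_equal(mean(m$elongation), mean(tv$elongation), tolerance = 0.05)
  s <- attr(m, "summary")
  expect_setequal(s$metric, c("roundness_pct", "elongation"))

  empty <- label(matrix(FALSE, 5, 5))
  expect_equal(nrow(measure_all(empty, 0.07)), 0)
})
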