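test_that("shortest distances follow voxel geometry under anisotropic spacing", {
  a <- array(FALSE, c(10, 10, 6)); b <- array(FALSE, c(10, 10, 6))
  a[5, 5, 3] <- TRUE
  b[8, 9, 3] <- TRUE   # offset (3, 4, 0) voxels
  sp <- c(0.07, 0.07, 0.08)
  expect_equal(shortest_distance(a, b, sp), 5 * 0.07, tolerance = 1e-12)
  # pure z offset uses the z step
  b2 <- array(FALSE, c(10, 10, 6)); b2[5, 5, 4] <- TRUE
  expect_equal(shortest_distance(a, b2, sp), 0.08, tolerance = 1e-12)
  # overlap gives zero
  expect_equal(shortest_distance(a, a | b, sp), 0)
  # symmetry as point sets
  expect_equal(shortest_distance(a, b, sp),
               shortest_distance(b, a, sp), tolerance = 1e-12)
  # empty reference flagged
  expect_warning(dd <- shortest_distance(a, array(FALSE, c(10, 10, 6)), sp),
                 "empty")
  expect_true(is.infinite(dd))
  expect_error(shortest_distance(array(FALSE, c(10, 10, 6)), b, sp), "empty")
})

test_that("distance-transform distances equal brute force on scene objects", {
  sc <- make_er_scene_3d(n_marker = 6, n_endosome = 8, attach_fraction = 0.5,
                         noise = noise_none(), seed = 17)
  er <- sc$truth$masks$ER
  endo <- label(sc$truth$masks$SNX1)
  sp <- c(0.07, 0.07, 0.08)
  dmap <- edt_of_mask(er, sp)
  for (id in seq_len(attr(endo, "n"))) {
    vox <- which(endo == id)
    expect_lte(length(vox), 500)
    expect_equal(min(dmap[vox]), bf_shortest_distance(vox, er, sp),
                 tolerance = 1e-9)
  }
})

test_that("triple classification recovers the planted attach fraction", {
  sc <- make_er_scene_3d(n_marker = 12, n_endosome = 10, attach_fraction = 1,
                         noise = noise_none(), seed = 19)
  sp <- c(0.07, 0.07, 0.08)
  endo <- label(sc$truth$masks$SNX1)
  pr <- classify_objects(endo, sc$truth$masks$ER, sc$truth$masks$DFCP1,
                         d_max = 0.15, spacing = sp)
  expect_equal(pr$pct_triple, 100)

  sc0 <- make_er_scene_3d(n_marker = 8, n_endosome = 10, attach_fraction = 0,
                          gap_dist = c(1, 0), noise = noise_none(), seed = 20)
  endo0 <- label(sc0$truth$masks$SNX1)
  pr0 <- classify_objects(endo0, sc0$truth$masks$ER, sc0$truth$masks$DFCP1,
                          d_max = 0.2, spacing = sp)
  expect_equal(pr0$pct_triple, 0)
  expect_true(all(pr0$records$class == "none"))

  mixed <- make_er_scene_3d(n_marker = 8, n_endosome = 12,
                            attach_fraction = 0.5, gap_dist = c(0.9, 0.05),
                            noise = noise_none(), seed = 21)
  endom <- label(mixed$truth$masks$SNX1)
  prm <- classify_objects(endom, mixed$truth$masks$ER, mixed$truth$masks$DFCP1,
                          d_max = 0.2, spacing = sp,
                          roi_area_um2 = mixed$truth$roi_area_um2)
  expect_equal(prm$pct_triple, 50)
  expect_equal(prm$density_per_ref_area,
               per_area(prm$n_triple, mixed$truth$roi_area_um2, 100))
  # classes match thresholding the recorded distances
  with(prm$records, expect_true(all(
    (class == "triple") == (d_to_er_um <= 0.2 & d_to_marker_um <= 0.2))))
})

test_that("the triple percentage is non-decreasing in d_max", {
  sc <- make_er_scene_3d(n_marker = 8, n_endosome = 12, attach_fraction = 0.5,
                         gap_dist = c(0.8, 0.1), noise = noise_none(), seed = 23)
  sp <- c(0.07, 0.07, 0.08)
  endo <- label(sc$truth$masks$SNX1)
  pcts <- vapply(c(0, 0.1, 0.3, 0.6, 1.2), function(dm)
    classify_objects(endo, sc$truth$masks$ER, sc$truth$masks$DFCP1,
                     d_max = dm, spacing = sp)$pct_triple, 0)
  expect_true(all(diff(pcts) >= 0))
})

test_that("segmentation-based 3D analysis matches mask-truth analysis", {
  sc <- make_er_scene_3d(n_marker = 6, n_endosome = 8, attach_fraction = 0.5,
                         noise = noise_none(), seed = 25)
  sp <- c(0.07, 0.07, 0.08)
  endo <- label(binarize(sc$image, "SNX1", method = "fixed", threshold = 1))
  er <- binarize(sc$image, "ER", method = "fixed", threshold = 1)
  mk <- binarize(sc$image, "DFCP1", method = "fixed", threshold = 1)
  pr <- classify_objects(endo, er, mk, d_max = 0.2, spacing = sp)
  expect_equal(pr$pct_triple, 50)
  expect_equal(attr(endo, "n"), 8L)
})
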