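test_that("scene generators are deterministic given a seed", {
  a <- make_vesicle_scene(n_round = 4, n_elongated = 2, seed = 1)
  b <- make_vesicle_scene(n_round = 4, n_elongated = 2, seed = 1)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$vesicles, b$truth$vesicles)
  c <- make_vesicle_scene(n_round = 4, n_elongated = 2, seed = 2)
  expect_false(identical(a$image$data, c$image$data))

  t1 <- make_tubule_scene(n_tubules = 3, branch_count = 1, seed = 5)
  t2 <- make_tubule_scene(n_tubules = 3, branch_count = 1, seed = 5)
  expect_identical(t1$image$data, t2$image$data)
  expect_identical(t1$truth$puncta, t2$truth$puncta)

  e1 <- make_er_scene_3d(n_marker = 4, n_endosome = 4, seed = 3)
  e2 <- make_er_scene_3d(n_marker = 4, n_endosome = 4, seed = 3)
  expect_identical(e1$image$data, e2$image$data)
  expect_identical(e1$truth$endosomes, e2$truth$endosomes)
})

test_that("noiseless rasterized support equals the ground-truth mask", {
  sc <- make_vesicle_scene(n_round = 5, n_elongated = 3, noise = noise_none(),
                           seed = 2, amplitude = 100)
  ch <- get_channel(sc$image, "EEA1")
  expect_identical(unname(ch > 0), unname(sc$truth$masks$EEA1))
  # support recovered as the right number of connected components
  labs <- label(ch > 0)
  expect_equal(attr(labs, "n"), 8L)

  ts <- make_tubule_scene(n_tubules = 3, branch_count = 0,
                          noise = noise_none(), seed = 1)
  expect_identical(unname(get_channel(ts$image, "SNX1") > 0),
                   unname(ts$truth$masks$SNX1))
})

test_that("planted ellipse morphometry matches moment computation on its mask", {
  sc <- make_vesicle_scene(n_round = 0, n_elongated = 1,
                           aspect_range = c(2, 2),
                           radius_range_um = c(0.5, 0.5),
                           noise = noise_none(), seed = 4)
  mask <- sc$truth$masks$EEA1
  expect_equal(as.numeric(elongation(mask)), 2, tolerance = 0.05)
})

test_that("empty-scene background matches the noise model within 3 SE", {
  nm <- noise_model(background = 10, gain = 1, read_sd = 2, psf_sigma = 0)
  sc <- make_vesicle_scene(n_round = 0, n_elongated = 0, noise = nm, seed = 9,
                           field_um = c(8, 8))
  px <- get_channel(sc$image, "EEA1")
  # Poisson(10) + N(0, 2), clipped at 0: sd ~ sqrt(10 + 4)
  se <- sqrt(10 + 4) / sqrt(length(px))
  expect_lt(abs(mean(px) - 10), 3 * se)
})

test_that("tubule ground truth accounts branches and arclengths consistently", {
  sc <- make_tubule_scene(n_tubules = 4, branch_count = 3,
                          noise = noise_none(), seed = 6)
  tr <- sc$truth
  expect_equal(nrow(tr$branches), 3)
  expect_equal(tr$n_branch_nodes, 3)
  expect_equal(sum(tr$tubules$n_branches), 3)
  expect_equal(tr$tubules$total_length_um,
               tr$tubules$length_um + vapply(tr$tubules$id, function(i)
                 sum(tr$branches$length_um[tr$branches$tubule == i]), 0))
  # planted lengths match their polylines
  for (i in tr$tubules$id) {
    pl <- tr$polylines_um[[i]]
    expect_equal(tr$tubules$length_um[i],
                 sum(sqrt(rowSums(diff(pl)^2))), tolerance = 1e-9)
  }
})

test_that("3D scene plants attached endosomes at zero distance and gaps on target", {
  att <- make_er_scene_3d(n_marker = 10, n_endosome = 8, attach_fraction = 1,
                          noise = noise_none(), seed = 11)
  expect_true(all(att$truth$endosomes$d_er_um == 0))
  expect_true(all(att$truth$endosomes$d_marker_um == 0))

  gap <- make_er_scene_3d(n_marker = 6, n_endosome = 6, attach_fraction = 0,
                          gap_dist = c(1.0, 0), noise = noise_none(), seed = 12)
  # grid quantization: planted gap realized within a voxel diagonal
  expect_true(all(abs(gap$truth$endosomes$d_er_um - 1.0) <= 0.1))
  expect_true(all(gap$truth$endosomes$planted_gap_um == 1.0))
})

test_that("infeasible packings error out instead of looping forever", {
  expect_error(make_vesicle_scene(n_round = 400, n_elongated = 0,
                                  field_um = c(4, 4), seed = 1,
                                  max_tries = 50),
               "infeasible")
})
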