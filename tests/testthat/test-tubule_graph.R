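make_bar_mask <- function(len_px, width_px = 3L, size = NULL, horizontal = TRUE) {
  if (is.null(size)) size <- len_px + 10L
  m <- matrix(FALSE, max(width_px + 10L, 16L), size)
  r0 <- nrow(m) %/% 2
  m[r0:(r0 + width_px - 1L), 6:(5 + len_px)] <- TRUE
  if (horizontal) m else t(m)
}

test_that("skeletonization thins a bar to a single spanning path", {
  bar <- make_bar_mask(60)
  sk <- skeletonize(bar)
  expect_true(any(sk))
  g <- build_graph(sk, pixel_size = 0.1, prune_spur_um = 0)
  expect_equal(length(g$edges), 1L)
  expect_equal(sum(g$nodes$kind == "junction"), 0L)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2L)
  expect_false(any(skeletonize(matrix(FALSE, 8, 8))))
})

test_that("a disk skeleton has no long endpoint chains", {
  disk <- raster_disk(12)
  sk <- skeletonize(disk)
  g <- build_graph(sk, pixel_size = 1, prune_spur_um = 0)
  if (length(g$edges)) {
    ends <- g$nodes$id[g$nodes$degree == 1L]
    for (e in g$edges) {
      if (e$from %in% ends || e$to %in% ends)
        expect_lt(e$length_um, 12)
    }
  }
  succeed()
})

test_that("Y-shaped skeletons give one junction and prune away short arms", {
  m <- matrix(FALSE, 41, 41)
  m[21, 3:21] <- TRUE                  # west arm
  for (k in 0:16) { m[21 - k, 21 + k] <- TRUE }  # northeast arm
  for (k in 0:16) { m[21 + k, 21 + k] <- TRUE }  # southeast arm
  g <- build_graph(m, pixel_size = 0.1, prune_spur_um = 0)
  expect_equal(sum(g$nodes$kind == "junction"), 1L)
  expect_equal(sum(g$nodes$kind == "endpoint"), 3L)
  expect_equal(count_triple_connections(g)$count, 1L)

  # add a tiny third arm and prune it away
  m2 <- matrix(FALSE, 41, 41)
  m2[21, 3:39] <- TRUE
  m2[20:18, 21] <- TRUE  # 3-px spur, 0.3 um at 0.1 um/px
  gkeep <- build_graph(m2, pixel_size = 0.1, prune_spur_um = 0)
  expect_equal(count_triple_connections(gkeep)$count, 1L)
  gprune <- build_graph(m2, pixel_size = 0.1, prune_spur_um = 0.45)
  expect_equal(count_triple_connections(gprune)$count, 0L)
  expect_equal(length(gprune$edges), 1L)
})

test_that("node degrees equal twice the edge incidences", {
  for (s in 1:3) {
    sc <- make_tubule_scene(n_tubules = 3, branch_count = 2,
                            noise = noise_none(), seed = s)
    mask <- binarize(sc$image, "SNX1", method = "fixed", threshold = 1)
    g <- build_graph(skeletonize(mask), sc$image$pixel_size_xy)
    expect_equal(sum(g$nodes$degree), 2L * length(g$edges))
  }
})

test_that("raising the spur threshold never increases the junction count", {
  sc <- make_tubule_scene(n_tubules = 4, branch_count = 3,
                          noise = noise_model(psf_sigma = 0.08), seed = 13)
  mask <- binarize(sc$image, "SNX1")
  sk <- skeletonize(mask)
  counts <- vapply(c(0, 0.1, 0.25, 0.5, 1), function(p)
    count_triple_connections(build_graph(sk, sc$image$pixel_size_xy,
                                         prune_spur_um = p))$count, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("straight-bar length is measured within 5 percent at any angle", {
  px <- 0.07
  for (ang in c(0, 22.5, 45, 10) * pi / 180) {
    # 10 um bar at angle ang, radius 0.12 um
    m <- matrix(FALSE, 200, 200)
    p0 <- c(3, 7); p1 <- p0 + 10 * c(cos(ang), sin(ang))
    m <- endoquant:::rasterize_tube_segment(m, p0, p1, 0.12, px)
    g <- build_graph(skeletonize(m), px, mask = m)
    expect_equal(length(g$edges), 1L)
    expect_equal(g$edges[[1]]$length_um, 10, tolerance = 0.05 * 10)
  }
})

test_that("tubule counting applies the minimum-length filter per component", {
  px <- 0.1
  m <- matrix(FALSE, 60, 120)
  m <- endoquant:::rasterize_tube_segment(m, c(1, 2), c(4, 2), 0.2, px)   # 3 um
  m <- endoquant:::rasterize_tube_segment(m, c(1, 4), c(7, 4), 0.2, px)   # 6 um
  g <- build_graph(skeletonize(m), px, roi_area_um2 = 100, mask = m)
  tm <- measure_tubules(g, min_length_um = 1)
  expect_equal(tm$n_tubules, 2L)
  expect_equal(tm$n_per_area, 2)
  expect_equal(sort(tm$lengths_um), c(3, 6), tolerance = 0.05 * 3)
  tm2 <- measure_tubules(g, min_length_um = 4)
  expect_equal(tm2$n_tubules, 1L)
  expect_equal(tm2$lengths_um, 6, tolerance = 0.05 * 6)
  empty <- build_graph(matrix(FALSE, 5, 5), px)
  expect_equal(measure_tubules(empty)$n_tubules, 0L)
})

test_that("planted branch count and lengths recover on a noise-free scene", {
  sc <- make_tubule_scene(n_tubules = 5, branch_count = 3,
                          noise = noise_none(), seed = 21)
  mask <- binarize(sc$image, "SNX1", method = "fixed", threshold = 1)
  g <- build_graph(skeletonize(mask), sc$image$pixel_size_xy, mask = mask)
  expect_equal(count_triple_connections(g)$count, 3L)
  tm <- measure_tubules(g)
  expect_equal(tm$n_tubules, 5L)
  m <- sort(tm$lengths_um); p <- sort(sc$truth$tubules$total_length_um)
  expect_true(all(abs(m - p) / p < 0.05))
})
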