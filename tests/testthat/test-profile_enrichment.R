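test_that("profiles reproduce constant and linear intensity fields exactly", {
  const <- calibrated_image(matrix(7.5, 32, 32), "c", 0.1)
  line <- rbind(c(4, 16), c(28, 16))
  pr <- sample_profile(const, line)
  expect_true(all(abs(pr$intensity[, "c"] - 7.5) < 1e-12))
  expect_true(all(diff(pr$s_um) > 0))

  # bilinear interpolation is exact on a linear ramp
  ramp <- calibrated_image(matrix(rep(seq_len(32), each = 32), 32, 32) * 1.0,
                           "c", 0.1)
  # the ramp increases along x: value at pixel col c is c
  pr2 <- sample_profile(ramp, rbind(c(2, 16), c(30, 16)))
  expected <- 2 + pr2$s_um / 0.1  # x_px = 2 + s/px; value = x_px + 0.5 center
  expect_equal(unname(pr2$intensity[, "c"]), expected + 0.5, tolerance = 1e-9)
})

test_that("diagonal sampling matches a dense resampling oracle", {
  set.seed(5)
  # smooth random field: sum of a few broad Gaussians
  f <- matrix(0, 48, 48)
  for (k in 1:6)
    f <- endoquant:::add_gaussian_spot(f, runif(1, 1, 4), runif(1, 1, 4),
                                       runif(1, 20, 80), 0.8, 0.1)
  img <- calibrated_image(f, "c", 0.1)
  poly <- rbind(c(5, 6), c(40, 35))
  pr <- sample_profile(img, poly, step_um = 0.05)
  # oracle: direct bilinear evaluation at the same arclength positions
  L <- sqrt(sum((poly[2, ] - poly[1, ])^2)) * 0.1
  for (i in seq_along(pr$s_um)) {
    t <- pr$s_um[i] / L
    p <- poly[1, ] + t * (poly[2, ] - poly[1, ])
    expect_equal(unname(pr$intensity[i, "c"]),
                 endoquant:::bilinear_sample(f, p[1], p[2]), tolerance = 1e-6)
  }
})

test_that("paired enrichment reads the target at reference extrema", {
  s <- seq(0, 5, by = 0.05)
  mkprof <- function(refv, tgtv) structure(
    list(s_um = s, intensity = cbind(ref = refv, target = tgtv),
         channels = c("ref", "target"), polyline = NULL, tubule_id = 1),
    class = "profile_record")
  # constant target: both values zero after min subtraction
  p1 <- paired_enrichment(mkprof(sin(s) + 2, rep(4, length(s))), "ref", "target")
  expect_equal(p1$value_plus, 0)
  expect_equal(p1$value_minus, 0)
  # coincident single peak of height delta over baseline b
  b <- 10; delta <- 25
  bump <- exp(-(s - 2)^2 / 0.02)
  p2 <- paired_enrichment(mkprof(5 + 100 * bump, b + delta * bump),
                          "ref", "target")
  expect_equal(p2$value_plus, delta, tolerance = 1e-6)
  expect_equal(p2$value_minus, 0, tolerance = 1e-6)
  expect_equal(p2$x_plus_um, 2, tolerance = 0.05)
  # ties resolve to the smallest arclength
  p3 <- paired_enrichment(mkprof(rep(1, length(s)), rep(2, length(s))),
                          "ref", "target")
  expect_equal(p3$x_plus_um, 0)
  expect_equal(p3$x_minus_um, 0)
  # shift invariance of the target channel
  p4 <- paired_enrichment(mkprof(5 + 100 * bump, 50 + b + delta * bump),
                          "ref", "target")
  expect_equal(p4$value_plus, p2$value_plus, tolerance = 1e-9)
  expect_equal(p4$value_minus, p2$value_minus, tolerance = 1e-9)
  expect_error(paired_enrichment(p1, "ref", "target"), "profile_record")
})

test_that("cohort summaries handle degenerate pair sets by convention", {
  same <- data.frame(value_plus = c(3, 4, 5), value_minus = c(3, 4, 5))
  cs <- cohort_summary(same)
  expect_equal(cs$mean_diff, 0)
  expect_equal(cs$t_statistic, 0)
  expect_equal(cs$p_value, 1)
  const <- data.frame(value_plus = c(3, 4, 5), value_minus = c(1, 2, 3))
  expect_warning(cs2 <- cohort_summary(const), "zero-variance")
  expect_true(cs2$degenerate)
  expect_equal(cs2$mean_diff, 2)
  expect_true(is.na(cs2$p_value))
  expect_error(cohort_summary(same[1, , drop = FALSE]), "at least 2")
})

test_that("planted delta is recovered within 2 SE on generated scenes", {
  nm <- noise_model(background = 10, gain = 1, read_sd = 2, psf_sigma = 0)
  sc <- make_tubule_scene(n_tubules = 20, branch_count = 0, noise = nm,
                          seed = 12, field_um = c(26, 26),
                          puncta_model = list(n_ref = 3, n_target = 3,
                                              delta = 60, rho = 1))
  pairs <- do.call(rbind, lapply(seq_along(sc$truth$polylines_px), function(i) {
    pr <- sample_profile(sc$image, sc$truth$polylines_px[[i]],
                         step_um = 0.035, tubule_id = i)
    paired_enrichment(pr, "LC3", "SNX2")
  }))
  cs <- cohort_summary(pairs)
  se <- cs$sd_diff / sqrt(cs$n)
  expect_lt(abs(cs$mean_diff - 60), 2 * se)
  expect_true(all(pairs$value_plus >= 0 & pairs$value_minus >= 0))
})

test_that("independent channels give a centered null and monotone power in delta", {
  # null: mean difference near zero across cohorts
  md <- vapply(1:40, function(r) {
    profs <- simulate_enrichment_cohort(n_tubules = 20, rho = 0, seed = r)
    prs <- do.call(rbind, lapply(profs, paired_enrichment,
                                 ref_channel = "ref", target_channel = "target"))
    mean(prs$value_plus - prs$value_minus)
  }, 0)
  se <- sd(md) / sqrt(length(md))
  expect_lt(abs(mean(md)), 3 * se + 1)
  # expectation increases with delta under full colocalization
  mean_at_delta <- function(d) {
    profs <- simulate_enrichment_cohort(n_tubules = 40, rho = 1, delta = d,
                                        noise_sd = 2, seed = 99)
    prs <- do.call(rbind, lapply(profs, paired_enrichment,
                                 ref_channel = "ref", target_channel = "target"))
    mean(prs$value_plus - prs$value_minus)
  }
  ms <- vapply(c(10, 30, 60, 90), mean_at_delta, 0)
  expect_true(all(diff(ms) > 0))
})
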