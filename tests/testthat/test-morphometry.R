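test_that("preprocessing binarizes boundary-stained images correctly", {
  mos <- simulate_fiber_mosaic(30, 2500, boundary_intensity = 255,
                               interior_intensity = 0, noise_sd = 0, seed = 1)
  # without smoothing, a two-level image recovers the interior exactly
  cfg <- morphometry_config(gaussian_sigma_px = 0)
  bin <- preprocess_image(mos$image, cfg)
  expect_identical(bin$pixels > 0, mos$label_map > 0)

  # with noise, disagreement with the ground-truth interior stays < 2%
  noisy <- simulate_fiber_mosaic(30, 2500, noise_sd = 10, seed = 2)
  bin2 <- preprocess_image(noisy$image, morphometry_config())
  expect_lt(mean((bin2$pixels > 0) != (noisy$label_map > 0)), 0.02)

  expect_error(preprocess_image(image_grid(matrix(7, 5, 5))), "no contrast")
})

test_that("segmentation recovers disjoint fibers and splits bridged ones", {
  mos <- simulate_fiber_mosaic(50, 5000, noise_sd = 0, seed = 3)
  reg <- segment_fibers(preprocess_image(mos$image), morphometry_config())
  expect_identical(sum(reg$status == "accepted"), 50L)

  img <- bridged_disks_image(r = 30, bridge_halfwidth = 1)
  cfg <- morphometry_config(gaussian_sigma_px = 0,
                            adhesion_opening_radius_px = 3)
  reg2 <- segment_fibers(preprocess_image(img, cfg), cfg)
  expect_identical(sum(reg2$status == "accepted"), 2L)

  # without opening the bridge keeps them fused
  cfg0 <- morphometry_config(gaussian_sigma_px = 0,
                             adhesion_opening_radius_px = 0)
  reg3 <- segment_fibers(preprocess_image(img, cfg0), cfg0)
  expect_identical(nrow(reg3), 1L)

  empty <- segment_fibers(
    structure(image_grid(matrix(0, 8, 8)), binary = TRUE))
  expect_identical(nrow(empty), 0L)
})

test_that("acceptance bounds are closed intervals with ordered reasons", {
  cfg <- morphometry_config()
  stubs <- tibble::tibble(
    area_px = c(1399, 1400, 80000, 80001, 5000, 5000, 5000),
    circularity = c(0.5, 0.5, 0.5, 0.5, 0.19, 0.2, 1.0),
    border_touching = FALSE)
  out <- classify_regions(stubs, cfg)
  expect_identical(out$reason[1], "too_small")
  expect_identical(out$status[2], "accepted")
  expect_identical(out$status[3], "accepted")
  expect_identical(out$reason[4], "too_large")
  expect_identical(out$reason[5], "non_circular")
  expect_identical(out$status[6:7], c("accepted", "accepted"))

  # border contact outranks any other failure
  both <- classify_regions(tibble::tibble(area_px = 10, circularity = 0.1,
                                          border_touching = TRUE), cfg)
  expect_identical(both$reason, "border_touching")
})

test_that("region filter matches a brute-force interval scan", {
  cfg <- morphometry_config()
  withr::with_seed(42, {
    stubs <- tibble::tibble(
      area_px = round(runif(2000, 0, 120000)),
      circularity = runif(2000, 0, 1.05),
      border_touching = runif(2000) < 0.1)
  })
  out <- classify_regions(stubs, cfg)
  brute <- !stubs$border_touching &
    stubs$area_px >= 1400 & stubs$area_px <= 80000 &
    stubs$circularity >= 0.2 & stubs$circularity <= 1.0
  expect_identical(out$status == "accepted", brute)
})

test_that("circularity follows the isoperimetric closed forms", {
  r <- 50
  expect_identical(circularity(pi * r^2, 2 * pi * r), 1)
  expect_lt(abs(circularity(1000, 220) - 4 * pi * 1000 / 220^2), 1e-12)
  expect_error(circularity(-1, 10), "positive")
  expect_error(circularity(10, 0), "positive")

  mask <- disk_mask(50)
  circ <- circularity(sum(mask), region_perimeter(mask))
  expect_gt(circ, 0.85)
  expect_lt(circ, 1.05)
})

test_that("perimeter is invariant under translation and 90-degree rotation", {
  blob <- disk_mask(12)
  blob[10:14, 5:23] <- TRUE  # asymmetric lobe
  p0 <- region_perimeter(blob)
  shifted <- matrix(FALSE, nrow(blob) + 6, ncol(blob) + 9)
  shifted[6 + seq_len(nrow(blob)), 9 + seq_len(ncol(blob))] <- blob
  expect_equal(region_perimeter(shifted), p0)
  expect_equal(region_perimeter(t(blob)), p0)
  expect_equal(region_perimeter(blob[nrow(blob):1, ]), p0)
})

test_that("fiber summaries compute the hypertrophy statistic", {
  expect_identical(hypertrophy_fraction(c(10, 15, 20), 14.2877), 2 / 3)
  expect_identical(hypertrophy_fraction(c(10, 15, 20), 5), 1)
  expect_identical(hypertrophy_fraction(c(10, 15, 20), 25), 0)

  # non-increasing step function of the threshold
  withr::with_seed(10, csa <- runif(200, 1000, 9000))
  grid <- seq(0, 10000, by = 250)
  fr <- vapply(grid, function(t) hypertrophy_fraction(csa, t), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_identical(fr[1], 1)
  expect_identical(fr[length(fr)], 0)

  mos <- simulate_fiber_mosaic(100, 5000, noise_sd = 0, seed = 5)
  reg <- segment_fibers(preprocess_image(mos$image), morphometry_config())
  sm <- summarize_fibers(reg, hypertrophy_threshold = 5000)
  expect_identical(sm$n_accepted, length(sm$csa_values))
  expect_lt(abs(sm$mean_csa - 5000) / 5000, 0.1)

  empty <- summarize_fibers(reg[0, ])
  expect_identical(empty$n_accepted, 0L)
  expect_true(is.na(empty$mean_csa))

  # calibrated output switches to square micrometres
  sm_um <- summarize_fibers(reg, um_per_px = 0.5)
  expect_identical(sm_um$csa_unit, "um2")
  expect_equal(sm_um$mean_csa, sm$mean_csa * 0.25)
})

test_that("fiber typing recovers the planted slow-twitch proportion", {
  atp <- simulate_atpase_image(0.4, n_fibers = 50, seed = 6)
  ft <- fiber_typing(atp$image)
  expect_identical(ft$proportion_slow, 0.4)
  expect_identical(ft$n_fibers, 50L)

  expect_warning(
    ft0 <- fiber_typing(simulate_atpase_image(0, 30, seed = 7)$image),
    "one class")
  expect_identical(ft0$proportion_slow, 0)
  expect_warning(
    ft1 <- fiber_typing(simulate_atpase_image(1, 30, seed = 8)$image),
    "one class")
  expect_identical(ft1$proportion_slow, 1)
})

test_that("group comparisons return standard two-sided tests", {
  same <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)), "two_sample_t")
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  withr::with_seed(11, {
    sep <- compare_groups(list(a = rnorm(4, 0, 0.01), b = rnorm(4, 10, 0.01)),
                          "two_sample_t")
  })
  expect_lt(sep$p_value, 0.001)

  expect_warning(
    deg <- compare_groups(list(a = c(5, 5, 5), b = c(5, 5, 5)), "two_sample_t"),
    "p = 1")
  expect_identical(deg$p_value, 1)

  # matches stats::oneway.test on a data-frame input
  df <- data.frame(value = c(1, 3, 2, 6, 7, 9, 4, 5, 6),
                   group = rep(c("x", "y", "z"), each = 3))
  got <- compare_groups(df, "one_way_anova")
  ref <- stats::oneway.test(value ~ group, df, var.equal = TRUE)
  expect_equal(got$p_value, ref$p.value)
  expect_error(compare_groups(list(a = 1:3), "one_way_anova"), "2 groups")
  expect_error(compare_groups(list(a = 1:3, b = 1:3, c = 1:3), "two_sample_t"),
               "exactly 2")
})

test_that("one-way ANOVA holds its size under the null", {
  withr::with_seed(12, {
    p <- replicate(400, {
      compare_groups(list(a = rnorm(5), b = rnorm(5), c = rnorm(5)),
                     "one_way_anova")$p_value
    })
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("images round-trip through TIFF and PNG", {
  mos <- simulate_fiber_mosaic(10, 900, seed = 9)
  dir <- withr::local_tempdir()
  for (ext in c("tif", "png")) {
    p <- file.path(dir, paste0("m.", ext))
    write_image_grid(mos$image, p)
    back <- read_image_grid(p)
    expect_identical(back$pixels, mos$image$pixels)
  }
})
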