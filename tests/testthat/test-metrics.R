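test_that("evaluation mask implements the boundary-inclusive annulus", {
  # full-resolution scanner grid: 100 B-scans x 1000 A-scans over 1.4 mm
  m <- make_eval_mask(c(100, 1000), spacing = c(1.4, 14.0, 0.78))
  ctr <- attr(m, "center")
  expect_false(m[round(ctr[1]) + 1, round(ctr[2]) + 1])  # r = 0 excluded
  # a point at r = 0.4 mm along x is included
  x_off <- round(400 / 1.4)
  expect_true(m[round(ctr[1]) + 1, round(ctr[2]) + 1 + x_off])
  # a point at r = 0.65 mm is outside the 1.2 mm-diameter circle
  x_off2 <- round(650 / 1.4)
  expect_false(m[round(ctr[1]) + 1, round(ctr[2]) + 1 + x_off2])
  # pixel count matches the analytic annulus area within 2%
  area_mm2 <- pi * (0.6^2 - 0.15^2)
  px_mm2 <- (1.4e-3) * (14e-3)
  expect_lt(abs(sum(m) - area_mm2 / px_mm2) / (area_mm2 / px_mm2), 0.02)
  expect_error(make_eval_mask(c(10, 10), c(1, 1), d_inner_mm = 1.2,
                              d_outer_mm = 0.3), "d_inner")
})

test_that("border error is the masked mean/SD of unsigned differences in um", {
  a <- matrix(100, 4, 6)
  expect_equal(border_error(a, a)[c("mean", "sd")], c(mean = 0, sd = 0))
  b <- a + 3
  e <- border_error(a, b, axial_spacing = 0.78)
  expect_equal(unname(e["mean"]), 2.34)
  expect_equal(unname(e["sd"]), 0)
  # symmetry and scale covariance
  set.seed(4)
  b2 <- a + rnorm(24)
  e1 <- border_error(a, b2, axial_spacing = 0.78)
  e2 <- border_error(b2, a, axial_spacing = 0.78)
  expect_identical(e1, e2)
  e4 <- border_error(a, b2, axial_spacing = 1.56)
  expect_equal(unname(e4[c("mean", "sd")]), 2 * unname(e1[c("mean", "sd")]))
  # folded-normal limit: mean |N(0, s^2)| -> s * sqrt(2/pi)
  set.seed(5)
  big <- matrix(rnorm(2e5, sd = 2), 400, 500)
  ef <- border_error(matrix(0, 400, 500), big)
  expect_lt(abs(ef[["mean"]] - 2 * sqrt(2 / pi)) / (2 * sqrt(2 / pi)), 0.02)
  # NA columns are excluded pairwise; empty masks error
  an <- a; an[1, 1] <- NA
  expect_equal(unname(border_error(an, b)["n"]), 23)
  expect_error(border_error(an, b, mask = matrix(FALSE, 4, 6)), "no valid")
})

test_that("variability tables separate intra, inter and automated comparisons", {
  ph <- generate_phantom(noiseless_params(c(10, 64, 448)), seed = 13)
  mask <- matrix(TRUE, 10, 64)
  r <- rater_model(sd_um = 1.0, spacing_px = 1)
  d1 <- simulate_rater(ph$truth, r, 0:9, seed = 41, rater_id = "r1")
  d1r <- simulate_rater(ph$truth, r, 0:9, seed = 42, rater_id = "r1",
                        repeat_id = "rep1")
  d2 <- simulate_rater(ph$truth, r, 0:9, seed = 43, rater_id = "r2")
  tabs <- variability_tables(list(d1, d1r, d2), surfaces_auto = ph$truth$surfaces,
                             mask = mask, spacing = ph$volume$spacing)
  expect_true(all(c("rater", "surface", "n_slices", "mean_um", "sd_um") %in%
                    names(tabs$intra)))
  expect_equal(unique(tabs$intra$n_slices), 10)
  # inter-rater means near the folded-normal expectation for sigma = 1 um
  expect_lt(abs(mean(tabs$inter$mean_um) - 2 / sqrt(pi)) / (2 / sqrt(pi)), 0.1)
  # the automated rows compare truth-as-auto against noisy raters: same scale
  expect_lt(abs(mean(tabs$auto$mean_um) - sqrt(2 / pi)) / sqrt(2 / pi), 0.1)

  # identical "raters": all inter entries zero
  d2b <- simulate_rater(ph$truth, rater_model(sd_um = 0, spacing_px = 1),
                        0:9, seed = 1, rater_id = "a")
  d3 <- simulate_rater(ph$truth, rater_model(sd_um = 0, spacing_px = 1),
                       0:9, seed = 2, rater_id = "b")
  expect_warning(
    tabs0 <- variability_tables(list(d2b, d3), mask = mask,
                                spacing = ph$volume$spacing),
    "no repeat")
  expect_true(all(tabs0$inter$mean_um < 1e-9))
  expect_null(tabs0$intra)
})

test_that("Bruch's membrane substitutes for an untraced ONL top", {
  shape <- c(4, 48, 448)
  sev <- matrix(1, shape[1], shape[2])
  ph <- generate_phantom(phantom_params(shape = shape, mode = "ld",
                                        ld_severity = sev, speckle_shape = Inf,
                                        noise_sd = 0, jitter_sd_voxels = 0,
                                        n_vessels = 0, onh_radius_mm = 0,
                                        onh_depth_um = 0), seed = 14)
  mask <- matrix(TRUE, shape[1], shape[2])
  # the rater never traced ONL-Top (not visible post ablation)
  d <- simulate_rater(ph$truth, rater_model(sd_um = 0, spacing_px = 1), 0:3,
                      seed = 1, rater_id = "r1",
                      surfaces = setdiff(surface_names("ld"), "ONL-Top"))
  tabs <- suppressWarnings(  # a single tracing: the intra table is empty
    variability_tables(list(d), surfaces_auto = ph$truth$surfaces,
                       mask = mask, spacing = ph$volume$spacing))
  auto_onl <- tabs$auto[tabs$auto$surface == "ONL-Top", ]
  expect_equal(nrow(auto_onl), 1)
  expect_equal(auto_onl$n_slices, 4)   # evaluated on every slice via the BM
  expect_true(all(auto_onl$mean_um < 1e-9))
})
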