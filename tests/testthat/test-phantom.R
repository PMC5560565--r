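test_that("phantom generation is reproducible and truth is ordered", {
  p <- phantom_params(shape = c(4, 32, 448))
  a <- generate_phantom(p, seed = 5)
  b <- generate_phantom(p, seed = 5)
  expect_identical(a$volume$intensity, b$volume$intensity)
  expect_identical(a$truth$surfaces$surfaces, b$truth$surfaces$surfaces)
  c2 <- generate_phantom(p, seed = 6)
  expect_false(identical(a$volume$intensity, c2$volume$intensity))
  s <- a$truth$surfaces$surfaces
  for (i in seq_len(length(s) - 1))
    expect_true(all(s[[i + 1]] - s[[i]] >= -1e-9))
})

test_that("the noiseless flat limit is exactly piecewise-constant per layer", {
  p <- phantom_params(shape = c(2, 8, 448), speckle_shape = Inf, noise_sd = 0,
                      jitter_sd_voxels = 0, n_vessels = 0, onh_radius_mm = 0,
                      onh_depth_um = 0, undulation_amplitude_um = 0,
                      ilm_depth_um = 78)  # 100 voxels exactly at 0.78 um
  ph <- generate_phantom(p, seed = 1)
  col <- ph$volume$intensity[1, 1, ]
  # layer thicknesses 12/39/25/14/53/14/8/10/15 um are not all integer voxel
  # multiples, so check the unambiguous plateaus
  expect_true(all(col[1:100] == 0.05))                     # vitreous
  ilm <- ph$truth$surfaces$surfaces$ILM[1, 1]
  expect_equal(ilm, 100)
  expect_true(all(col[101:115] == 0.85))                   # RNFGC plateau
  bm <- ph$truth$surfaces$surfaces$BM[1, 1]
  expect_true(all(col[(ceiling(bm) + 2):448] == 0.12))     # choroid
})

test_that("configured ONL thickness is honoured exactly outside the ONH", {
  p <- phantom_params(shape = c(6, 48, 448))
  ph <- generate_phantom(p, seed = 3)
  s <- ph$truth$surfaces$surfaces
  onl_um <- (s$ELM - s$`OPL-ONL`) * p$spacing[3]
  # columns outside the ONH disc (radius 0.15 mm around the centre)
  mask <- make_eval_mask(c(6, 48), p$spacing, d_inner_mm = 0.3, d_outer_mm = 10)
  expect_true(all(abs(onl_um[mask] - 53) < 1e-9))
})

test_that("full regional ablation collapses the true ONL top onto Bruch's membrane", {
  shape <- c(4, 32, 448)
  sev <- matrix(0, shape[1], shape[2]); sev[, 17:32] <- 1
  p <- phantom_params(shape = shape, mode = "ld", ld_severity = sev)
  ph <- generate_phantom(p, seed = 2)
  s <- ph$truth$surfaces$surfaces
  expect_true(all(abs(s$`ONL-Top`[, 17:32] - s$BM[, 17:32]) < 1e-9))
  expect_true(all(s$BM[, 1:16] - s$`ONL-Top`[, 1:16] > 1))
  expect_equal(names(s), surface_names("ld"))
  # severity 1 everywhere
  p1 <- phantom_params(shape = shape, mode = "ld", ld_severity = 1)
  ph1 <- generate_phantom(p1, seed = 2)
  s1 <- ph1$truth$surfaces$surfaces
  expect_true(all(abs(s1$`ONL-Top` - s1$BM) < 1e-9))
})

test_that("per-B-scan jitter has the configured magnitude", {
  p <- phantom_params(shape = c(120, 4, 448), jitter_sd_voxels = 1.5,
                      undulation_amplitude_um = 0, onh_radius_mm = 0,
                      onh_depth_um = 0, speckle_shape = Inf, noise_sd = 0,
                      n_vessels = 0)
  ph <- generate_phantom(p, seed = 8)
  ilm <- ph$truth$surfaces$surfaces$ILM[, 1]
  offs <- diff(ilm)  # successive B-scan offsets: sd = sqrt(2) * jitter sd
  expect_lt(abs(stats::sd(offs) / sqrt(2) - 1.5) / 1.5, 0.2)
})

test_that("a stack that cannot fit the volume depth errors", {
  expect_error(phantom_params(shape = c(2, 8, 128)), "fit|exceed")
})

test_that("a noiseless rater reproduces truth at its control points", {
  ph <- generate_phantom(noiseless_params(c(4, 32, 448)), seed = 4)
  d <- simulate_rater(ph$truth, rater_model(bias_um = 0, sd_um = 0, spacing_px = 5),
                      slice_ids = c(0, 2), seed = 1)
  out <- delineation_to_surface(d, x_grid = seq(0, 31, by = 5))
  for (nm in c("ILM", "BM")) {
    for (b in c("0", "2")) {
      tr <- ph$truth$surfaces$surfaces[[nm]][as.integer(b) + 1, seq(1, 32, by = 5)]
      expect_equal(out[[nm]][[b]], tr, tolerance = 1e-9)
    }
  }
  expect_error(simulate_rater(ph$truth, rater_model(), integer(0)), "at least one")
})

test_that("two simulated raters differ by the folded-normal expectation", {
  # E|X - Y| for X, Y ~ N(0, sigma^2) is 2 sigma / sqrt(pi)
  ph <- generate_phantom(noiseless_params(c(40, 64, 448)), seed = 10)
  r <- rater_model(sd_um = 1.0, spacing_px = 1)
  d1 <- simulate_rater(ph$truth, r, 0:39, seed = 21, rater_id = "r1")
  d2 <- simulate_rater(ph$truth, r, 0:39, seed = 22, rater_id = "r2")
  e1 <- delineation_to_surface(d1, 0:63)
  e2 <- delineation_to_surface(d2, 0:63)
  diffs <- unlist(lapply(names(e1), function(nm)
    lapply(names(e1[[nm]]), function(b)
      abs(e1[[nm]][[b]] - e2[[nm]][[b]]) * 0.78)))
  expect_lt(abs(mean(diffs) - 2 / sqrt(pi)) / (2 / sqrt(pi)), 0.05)
})

test_that("repeat tracings reproduce the observed intra-rater magnitude", {
  # sd chosen so that 2 sigma / sqrt(pi) is about the 1.3 um reported scale
  ph <- generate_phantom(noiseless_params(c(12, 64, 448)), seed = 11)
  r <- rater_model(sd_um = 1.13, spacing_px = 1)
  d1 <- simulate_rater(ph$truth, r, 0:11, seed = 31, rater_id = "r1")
  d2 <- simulate_rater(ph$truth, r, 0:11, seed = 32, rater_id = "r1",
                       repeat_id = "rep")
  e1 <- delineation_to_surface(d1, 0:63)
  e2 <- delineation_to_surface(d2, 0:63)
  diffs <- unlist(lapply(names(e1), function(nm)
    lapply(names(e1[[nm]]), function(b)
      abs(e1[[nm]][[b]] - e2[[nm]][[b]]) * 0.78)))
  expect_lt(abs(mean(diffs) - 1.27), 0.32)  # magnitude check only
})

test_that("cohort draws follow the configured summaries", {
  tab <- data.frame(layer = "OR", group = c("control", "ld"), day = 6,
                    mean_um = c(113.08, 36.90), sd_um = c(1.97, 3.72))
  co <- generate_cohort(tab, n_per_group = 2500, seed = 12)
  ld <- co[co$group == "ld" & co$quadrant == "S", ]
  # CLT: sample mean within 3 standard errors
  expect_lt(abs(mean(ld$thickness_um) - 36.90), 3 * 3.72 / sqrt(2500))
  expect_lt(abs(stats::sd(ld$thickness_um) - 3.72), 0.3)

  degenerate <- generate_cohort(data.frame(layer = "X", group = "g", day = 1,
                                           mean_um = 50, sd_um = 0),
                                n_per_group = 5, seed = 1)
  expect_true(all(degenerate$thickness_um == 50))
  expect_error(generate_cohort(data.frame(layer = "X", group = "g", day = 1,
                                          mean_um = 50, sd_um = -1), 5, 1),
               "negative")
  # deterministic given the seed
  expect_identical(generate_cohort(tab, 5, seed = 3),
                   generate_cohort(tab, 5, seed = 3))
})
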