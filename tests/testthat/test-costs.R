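test_that("gradient cost minima sit on edges of the requested polarity", {
  Z <- 12
  col <- c(rep(0, 6), rep(10, 6))
  vol <- oct_volume(array(rep(col, each = 4), c(2, 2, Z)), c(1, 1, 1))
  cd <- gradient_cost(vol, "dark_to_bright", scale = 0.6, lateral_scale = 0)
  # per-column argmin on the step rows (either side of the edge)
  am <- which.min(cd[1, 1, ]) - 1
  expect_true(am %in% c(5, 6))
  expect_true(all(cd >= 0))
  # opposite polarity: the step is the cost *maximum*, no interior minimum there
  cb <- gradient_cost(vol, "bright_to_dark", scale = 0.6, lateral_scale = 0)
  expect_equal(which.max(cb[1, 1, ]) - 1, am)
  # linear ramp: constant derivative away from the borders
  ramp <- oct_volume(array(rep(0:(Z - 1), each = 4), c(2, 2, Z)), c(1, 1, 1))
  cr <- gradient_cost(ramp, "dark_to_bright", scale = 0.6, lateral_scale = 0)
  # interior rows only: edge-renormalized smoothing perturbs the first rows
  expect_lt(diff(range(cr[1, 1, 4:(Z - 3)])), 1e-9)
})

test_that("gradient cost is translation-equivariant along z", {
  set.seed(2)
  col <- c(runif(6), 5, runif(9))
  v1 <- oct_volume(array(col, c(1, 1, 16)), c(1, 1, 1))
  v2 <- oct_volume(array(c(0.5, col[1:15]), c(1, 1, 16)), c(1, 1, 1))
  c1 <- gradient_cost(v1, "dark_to_bright", scale = 1, lateral_scale = 0)
  c2 <- gradient_cost(v2, "dark_to_bright", scale = 1, lateral_scale = 0)
  expect_equal(which.min(c2[1, 1, 4:16]), which.min(c1[1, 1, 3:15]))
})

test_that("feature extraction honours the ROI contract", {
  B <- 2; X <- 4; Z <- 40
  vol <- oct_volume(array(0.5, c(B, X, Z)), c(1, 1, 1))
  roi <- list(ilm = matrix(10, B, X), bottom = matrix(30, B, X),
              zmin = 5L, zmax = 35L)
  st <- extract_features(vol, roi)
  expect_s3_class(st, "feature_stack")
  expect_equal(nrow(st$X), B * X * 31)
  # constant volume: all derivative features exactly zero
  expect_true(all(abs(st$X[, c("ddz1", "ddz2", "ddz1_neg", "ddz2_neg")]) < 1e-12))
  # relative depth is 0 at the ILM and 1 at the outer ROI boundary
  z_of_row <- rep(5:35, each = B * X)
  expect_true(all(st$X[z_of_row == 10, "rel_depth"] == 0))
  expect_true(all(st$X[z_of_row == 30, "rel_depth"] == 1))
  expect_true(all(st$X[, "rel_depth"] >= 0 & st$X[, "rel_depth"] <= 1))
  expect_error(extract_features(vol, list(ilm = roi$ilm, bottom = roi$bottom,
                                          zmin = 10L, zmax = 5L)),
               "empty|invalid")
})

test_that("smoothed intensity of an impulse reproduces the discrete Gaussian kernel", {
  B <- 1; X <- 9; Z <- 41
  arr <- array(0, c(B, X, Z))
  arr[1, 5, 21] <- 1
  vol <- oct_volume(arr, c(1, 1, 1))
  st <- extract_features(vol, list(ilm = matrix(5, B, X),
                                   bottom = matrix(35, B, X),
                                   zmin = 0L, zmax = Z - 1L))
  # independent closed-form kernel: truncated at 3 sigma, renormalized
  kz <- exp(-(-6:6)^2 / (2 * 2^2)); kz <- kz / sum(kz)
  kx <- exp(-(-3:3)^2 / (2 * 1^2)); kx <- kx / sum(kx)
  sm2 <- array(st$X[, "smooth2"], c(B, X, Z))
  expect_equal(sm2[1, 5, 15:27], kz * kx[4], tolerance = 1e-12)
  expect_equal(sm2[1, 4, 21], kz[7] * kx[3], tolerance = 1e-12)
})

test_that("classifier training is deterministic, balanced and reports OOB accuracy", {
  fit <- small_healthy_fit()
  m1 <- fit$models$stage1
  expect_s3_class(m1, "boundary_model")
  expect_gt(m1$oob_accuracy, 0.9)
  expect_equal(m1$classes, c("background", "ILM", "RNFGC-IPL"))

  # same data, same seed -> identical predictions
  vws <- downsample_volume(fit$ptest$volume, 2, 2)
  roi <- coarse_localize(vws, seg_config("healthy"))
  st <- extract_features(vws, roi)
  sub <- st
  sub$X <- st$X[seq(1, nrow(st$X), by = 97), , drop = FALSE]
  sub$dims <- c(nrow(sub$X), 1, 1)
  delin <- simulate_rater(fit$ptrain$truth, rater_model(sd_um = 1, spacing_px = 4),
                          slice_ids = c(1, 3, 5, 7, 9, 11), seed = 5)
  m2 <- train_segmentation_models(fit$ptrain$volume, delin, "healthy",
                                  seed = 42)$stage1
  p1 <- predict_costs(m1, sub)
  p2 <- predict_costs(m2, sub)
  expect_identical(p1, p2)
})

test_that("predicted costs are the affine complement of class probabilities", {
  fit <- small_healthy_fit()
  vws <- downsample_volume(fit$ptest$volume, 2, 2)
  roi <- coarse_localize(vws, seg_config("healthy"))
  st <- extract_features(vws, roi)
  st$X <- st$X[1:500, , drop = FALSE]
  st$dims <- c(500, 1, 1)
  costs <- predict_costs(fit$models$stage1, st)
  expect_named(costs, c("ILM", "RNFGC-IPL"))
  pr <- 1 - do.call(cbind, lapply(costs, as.numeric))
  # probabilities sum to at most one over the classes (background absorbs the rest)
  expect_true(all(rowSums(pr) <= 1 + 1e-9))
  expect_true(all(pr >= -1e-9 & pr <= 1 + 1e-9))

  stack_bad <- st
  stack_bad$recipe <- "other"
  expect_error(predict_costs(fit$models$stage1, stack_bad), "recipe mismatch")
})

test_that("training fails cleanly on missing annotations or single-class data", {
  fit <- small_healthy_fit()
  delin <- simulate_rater(fit$ptrain$truth, rater_model(sd_um = 1, spacing_px = 4),
                          slice_ids = c(1, 3), seed = 5,
                          surfaces = c("ILM"))
  vws <- downsample_volume(fit$ptrain$volume, 2, 2)
  roi <- coarse_localize(vws, seg_config("healthy"))
  st <- extract_features(vws, roi)
  delin_ws <- delineation(delin$rater, lapply(delin$slices, function(sl)
    list(b = sl$b, surface = sl$surface,
         points = cbind(sl$points[, 1] / 2, sl$points[, 2] / 2))))
  expect_error(
    train_boundary_classifier(st, delin_ws, c("ILM", "RNFGC-IPL"), "healthy"),
    "RNFGC-IPL")
})
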