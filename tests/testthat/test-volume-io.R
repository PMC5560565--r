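test_that("volume persistence round-trips intensity bit-exactly and spacing exactly", {
  v <- rand_volume(c(4, 8, 16))
  path <- withr::local_tempfile(fileext = ".tif")
  write_oct_volume(v, path)
  r <- read_oct_volume(path)
  expect_identical(r$intensity, v$intensity)
  expect_identical(r$spacing, v$spacing)
  expect_equal(r$metadata$mode, "healthy")
})

test_that("reader maps TIFF pages to (B, X, Z) and preserves sidecar spacing", {
  # scanner geometry scaled down: pages are A-scans x depth
  v <- rand_volume(c(5, 10, 32), seed = 3)
  path <- withr::local_tempfile(fileext = ".tif")
  write_oct_volume(v, path)
  pages <- octseg:::read_float_tiff(path)
  expect_length(pages, 5)
  expect_equal(dim(pages[[1]]), c(10, 32))
  r <- read_oct_volume(path)
  expect_equal(dim(r), c(5, 10, 32))
  # the full-field spacing of the reference geometry survives exactly
  expect_identical(r$spacing, c(x = 1.4, y = 14.0, z = 0.78))
})

test_that("missing sidecar errors with the expected path", {
  v <- rand_volume(c(2, 4, 8))
  path <- withr::local_tempfile(fileext = ".tif")
  write_oct_volume(v, path)
  file.remove(paste0(path, ".json"))
  expect_error(read_oct_volume(path), paste0(path, ".json"), fixed = TRUE)
})

test_that("float TIFF agrees with an independent reader", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  v <- rand_volume(c(3, 6, 10), seed = 9)
  path <- withr::local_tempfile(fileext = ".tif")
  write_oct_volume(v, path)
  out <- system2(py, c("-c", shQuote(paste0(
    "import tifffile, numpy as np; a = tifffile.imread('", path, "');",
    "print(a.shape); print(float(a.sum()))"))), stdout = TRUE)
  expect_equal(out[1], "(3, 6, 10)")
  expect_equal(as.numeric(out[2]), sum(v$intensity), tolerance = 1e-12)
})

test_that("downsampling block-averages laterally and axially, never across B-scans", {
  v <- rand_volume(c(4, 8, 16))
  d <- downsample_volume(v, 2, 2)
  expect_equal(dim(d), c(4, 4, 8))
  expect_identical(d$spacing, v$spacing * c(2, 1, 2))
  # explicit 1x2x2 block mean
  blk <- oct_volume(array(c(1, 5, 3, 7), c(1, 2, 2)), c(1, 1, 1))
  expect_equal(as.numeric(downsample_volume(blk, 2, 2)$intensity), 4)
  # identity and global-mean preservation
  expect_identical(downsample_volume(v, 1, 1), v)
  expect_equal(mean(d$intensity), mean(v$intensity))
})

test_that("non-divisible downsampling crops with a warning; bad factors error", {
  v <- rand_volume(c(2, 7, 9))
  expect_warning(d <- downsample_volume(v, 2, 2), "cropping")
  expect_equal(dim(d), c(2, 3, 4))
  expect_error(downsample_volume(v, 0, 1), "factors")
})

test_that("surface sets validate ordering and round-trip through TIFF + JSON", {
  s <- list(ILM = matrix(10.25, 2, 3), BM = matrix(20.5, 2, 3))
  ss <- surface_set(s)
  path <- withr::local_tempfile(fileext = ".tif")
  write_surface_set(ss, path)
  r <- read_surface_set(path)
  expect_equal(names(r$surfaces), c("ILM", "BM"))
  expect_equal(r$surfaces$ILM, s$ILM)
  expect_equal(r$units, "voxel")
  bad <- list(ILM = matrix(30, 2, 3), BM = matrix(20, 2, 3))
  expect_error(surface_set(bad), "ordering")
  # equality (zero-thickness collapse) is allowed
  expect_silent(surface_set(list(a = matrix(5, 1, 2), b = matrix(5, 1, 2))))
})

test_that("surface rescaling interpolates laterally and scales axially", {
  ss <- surface_set(list(s = matrix(c(10, 20), 1, 2)), resolution = "downsampled")
  r <- rescale_surfaces(ss, lateral_factor = 2, axial_factor = 1)
  expect_equal(as.numeric(r$surfaces$s), c(10, 15, 20, 20))
  flat <- surface_set(list(s = matrix(10, 2, 3)), resolution = "downsampled")
  expect_equal(unique(as.numeric(rescale_surfaces(flat, 1, 2)$surfaces$s)), 20)
  expect_equal(rescale_surfaces(flat, 1, 1)$surfaces$s, flat$surfaces$s)
})

test_that("delineations interpolate inside the span and stay missing outside", {
  pts <- cbind(c(2, 10), c(5, 9))
  d <- delineation("r1", list(list(b = 0L, surface = "ILM", points = pts)),
                   rule = "linear")
  out <- delineation_to_surface(d, x_grid = 0:12)
  z <- out$ILM[["0"]]
  expect_equal(z[3], 5)            # x = 2
  expect_equal(z[7], 7)            # x = 6, midpoint
  expect_equal(z[11], 9)           # x = 10
  expect_true(all(is.na(z[c(1, 2, 12, 13)])))  # outside span: missing

  # control points from one cubic polynomial, cubic rule: exact recovery
  f <- function(x) 1e-3 * x^3 - 0.04 * x^2 + 0.8 * x + 40
  xs <- seq(0, 28, by = 4)
  dc <- delineation("r1", list(list(b = 0L, surface = "ILM",
                                    points = cbind(xs, f(xs)))),
                    rule = "cubic")
  z <- delineation_to_surface(dc, x_grid = 0:28)$ILM[["0"]]
  expect_equal(z, f(0:28), tolerance = 1e-9)

  expect_error(
    delineation("r1", list(list(b = 0L, surface = "ILM",
                                points = matrix(c(1, 5), 1, 2)))),
    "2 control points")
})

test_that("delineations round-trip through JSON", {
  pts <- cbind(c(0, 7, 15), c(10.5, 11.25, 12))
  d <- delineation("rater2", list(list(b = 3L, surface = "BM", points = pts)),
                   rule = "natural", repeat_id = "rep1")
  path <- withr::local_tempfile(fileext = ".json")
  write_delineation(d, path)
  r <- read_delineation(path)
  expect_equal(r$rater, "rater2")
  expect_equal(r$repeat_id, "rep1")
  expect_equal(r$slices[[1]]$points, unname(pts))
  expect_equal(r$slices[[1]]$b, 3L)
})
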