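# Boundary cost functions: image gradients for the coarse stage, and
# per-voxel feature stacks feeding the random-forest boundary classifiers
# for the main stages.

# Truncated, renormalized 1-D Gaussian kernel (radius 3 sigma).
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Row-stochastic smoothing matrix for a length-n axis (edge-renormalized).
.smooth_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    w <- k[j - i + r + 1L]
    W[i, j] <- w / sum(w)
  }
  W
}

# Gaussian smoothing of a (B, X, Z) array along z (sigma_z) and x (sigma_x).
.smooth_volume <- function(arr, sigma_z, sigma_x = 0) {
  d <- dim(arr)
  if (sigma_z > 0) {
    Wz <- .smooth_matrix(d[3], sigma_z)
    m <- matrix(arr, d[1] * d[2], d[3])
    arr <- array(m %*% t(Wz), d)
  }
  if (sigma_x > 0 && d[2] > 1L) {
    Wx <- .smooth_matrix(d[2], sigma_x)
    a <- aperm(arr, c(2L, 1L, 3L))          # (X, B, Z)
    m <- matrix(a, d[2], d[1] * d[3])
    a <- array(Wx %*% m, c(d[2], d[1], d[3]))
    arr <- aperm(a, c(2L, 1L, 3L))
  }
  arr
}

# Central-difference axial derivative (one-sided at the ends).
.axial_derivative <- function(arr) {
  d <- dim(arr); Z <- d[3]
  out <- array(0, d)
  if (Z >= 3L)
    out[, , 2:(Z - 1)] <- (arr[, , 3:Z, drop = FALSE] - arr[, , 1:(Z - 2), drop = FALSE]) / 2
  out[, , 1] <- arr[, , min(2L, Z)] - arr[, , 1]
  out[, , Z] <- arr[, , Z] - arr[, , max(1L, Z - 1L)]
  out
}

#' Gradient-based boundary cost volume
#'
#' The cost is the negated signed axial derivative of the Gaussian-smoothed
#' intensity (sign chosen per edge polarity), shifted so that all costs are
#' non-negative. Minima lie on intensity edges of the requested polarity:
#' `"dark_to_bright"` favours transitions where intensity increases with
#' depth (e.g. vitreous to retina at the ILM), `"bright_to_dark"` the
#' reverse.
#'
#' @param volume an [oct_volume()] or 3-D intensity array `(b, x, z)`.
#' @param polarity `"dark_to_bright"` or `"bright_to_dark"`.
#' @param scale axial Gaussian smoothing scale in voxels (`> 0`).
#' @param lateral_scale lateral smoothing scale (defaults to half the axial
#'   scale).
#' @return a 3-D cost array of the same shape.
#' @export
gradient_cost <- function(volume, polarity = c("dark_to_bright", "bright_to_dark"),
                          scale = 2, lateral_scale = scale / 2) {
  polarity <- match.arg(polarity)
  arr <- if (inherits(volume, "oct_volume")) volume$intensity else volume
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop("`volume` must be an oct_volume or a 3-D array")
  if (scale <= 0) stop("`scale` must be > 0")
  sm <- .smooth_volume(arr, scale, lateral_scale)
  dz <- .axial_derivative(sm)
  cost <- if (polarity == "dark_to_bright") -dz else dz
  cost <- cost - min(cost)
  attr(cost, "polarity") <- polarity
  cost
}

.FEATURE_RECIPE <- "int-smooth124-ddz12-geom-v1"

#' Per-voxel boundary features within a region of interest
#'
#' Computes the feature stack consumed by the random-forest boundary
#' classifiers: raw intensity; Gaussian-smoothed intensity at scales 1, 2
#' and 4 voxels (axial; half laterally); signed axial derivatives at scales
#' 1 and 2 in both polarities; signed axial distance to the coarse ILM
#' estimate; relative depth within the ILM-to-outer-boundary ROI (clamped to
#' `[0, 1]`); and the normalized lateral position.
#'
#' @param volume an [oct_volume()] at the segmentation working resolution.
#' @param roi coarse region of interest as returned by [coarse_localize()]:
#'   a list with `ilm` and `bottom` (`B x X` matrices, voxels) and the depth
#'   band `zmin`, `zmax` (0-based, inclusive).
#' @return an object of class `feature_stack`: the feature matrix (rows in
#'   `(b, x, z)` order with `b` fastest), band bounds and the recipe id.
#' @export
extract_features <- function(volume, roi) {
  stopifnot(inherits(volume, "oct_volume"))
  if (!all(c("ilm", "bottom", "zmin", "zmax") %in% names(roi)))
    stop("`roi` must have elements ilm, bottom, zmin, zmax")
  d <- dim(volume)
  zmin <- as.integer(roi$zmin); zmax <- as.integer(roi$zmax)
  if (zmax < zmin || zmin < 0 || zmax > d[3] - 1L) stop("empty or invalid ROI depth band")
  arr <- volume$intensity
  sm1 <- .smooth_volume(arr, 1, 0.5)
  sm2 <- .smooth_volume(arr, 2, 1)
  sm4 <- .smooth_volume(arr, 4, 2)
  d1 <- .axial_derivative(sm1)
  d2 <- .axial_derivative(sm2)

  zidx <- (zmin:zmax) + 1L
  nz <- length(zidx)
  take <- function(a) as.vector(a[, , zidx, drop = FALSE])
  zg <- rep(zmin:zmax, each = d[1] * d[2])
  ilm <- rep(as.vector(roi$ilm), nz)
  bot <- rep(as.vector(roi$bottom), nz)
  depth <- pmax(bot - ilm, 1e-6)
  xg <- rep(rep((seq_len(d[2]) - 1L) / max(1L, d[2] - 1L), each = d[1]), nz)

  X <- cbind(
    intensity = take(arr),
    smooth1 = take(sm1),
    smooth2 = take(sm2),
    smooth4 = take(sm4),
    ddz1 = take(d1),
    ddz1_neg = -take(d1),
    ddz2 = take(d2),
    ddz2_neg = -take(d2),
    dist_ilm = zg - ilm,
    rel_depth = .clamp((zg - ilm) / depth, 0, 1),
    norm_x = xg
  )
  structure(
    list(X = X, dims = c(d[1], d[2], nz), zmin = zmin, zmax = zmax,
         recipe = .FEATURE_RECIPE),
    class = "feature_stack"
  )
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d voxels x %d features, z band [%d, %d] (%s)\n",
              nrow(x$X), ncol(x$X), x$zmin, x$zmax, x$recipe))
  invisible(x)
}
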