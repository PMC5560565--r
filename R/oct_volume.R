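# OCT volume container and resolution handling.
#
# Coordinate convention (fixed package-wide): intensity arrays are indexed
# (b, x, z) with 0-based positions in all numeric surface/ROI quantities;
# b runs over B-scans, x over A-scans within a B-scan, and z over depth with
# z = 0 on the vitreous (inner) side, increasing toward the sclera.

#' Construct an OCT volume
#'
#' @param intensity 3-D numeric array indexed `(b, x, z)`: B-scans by
#'   A-scans by depth. Values must be finite and non-negative.
#' @param spacing numeric length-3 voxel spacing in micrometres per voxel,
#'   ordered `(x, y, z)`: lateral A-scan pitch, B-scan pitch, axial depth.
#'   The scanner geometry used throughout as a default is a 1.4 x 1.4 x 1.6 mm
#'   field sampled as 1000 A-scans x 100 B-scans x 2048 depth voxels, i.e.
#'   spacing (1.4, 14.0, 0.78).
#' @param metadata named list of free-form scan metadata (id, eye, mode, ...).
#' @return an object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, spacing, metadata = list()) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("`intensity` must be a 3-D array indexed (b, x, z)")
  if (any(dim(intensity) < 1L)) stop("all volume dimensions must be >= 1")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("`intensity` must be finite")
  if (any(intensity < 0)) stop("`intensity` must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (x, y, z) in um/voxel")
  names(spacing) <- c("x", "y", "z")
  if (!is.list(metadata)) stop("`metadata` must be a list")
  structure(
    list(intensity = intensity, spacing = spacing, metadata = metadata),
    class = "oct_volume"
  )
}

#' @export
dim.oct_volume <- function(x) dim(x$intensity)

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<oct_volume> %d B-scans x %d A-scans x %d depth voxels\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing (um/voxel): x = %.4g, y = %.4g, z = %.4g\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Downsample a volume laterally and axially by block averaging
#'
#' Each B-scan is reduced by integer factors in the lateral (x) and axial (z)
#' directions; the number of B-scans is never altered. Output voxels are the
#' arithmetic means of the corresponding input blocks and the voxel spacing is
#' multiplied by the factors. Trailing rows/columns that do not fill a whole
#' block are cropped with a warning.
#'
#' @param volume an [oct_volume()].
#' @param lateral_factor,axial_factor integer factors `>= 1`.
#' @return a downsampled `oct_volume`.
#' @export
downsample_volume <- function(volume, lateral_factor = 2L, axial_factor = 2L) {
  stopifnot(inherits(volume, "oct_volume"))
  lf <- as.integer(lateral_factor); af <- as.integer(axial_factor)
  if (is.na(lf) || is.na(af) || lf < 1L || af < 1L)
    stop("downsampling factors must be integers >= 1")
  if (lf == 1L && af == 1L) return(volume)
  d <- dim(volume)
  X2 <- (d[2] %/% lf) * lf
  Z2 <- (d[3] %/% af) * af
  if (X2 < lf || Z2 < af) stop("volume too small for the requested factors")
  if (X2 != d[2] || Z2 != d[3])
    warning(sprintf("cropping volume from (%d, %d, %d) to (%d, %d, %d) before block averaging",
                    d[1], d[2], d[3], d[1], X2, Z2))
  v <- volume$intensity[, seq_len(X2), seq_len(Z2), drop = FALSE]
  out <- array(0, c(d[1], X2 %/% lf, Z2 %/% af))
  for (i in seq_len(lf)) {
    for (j in seq_len(af)) {
      out <- out + v[, seq(i, X2, by = lf), seq(j, Z2, by = af), drop = FALSE]
    }
  }
  out <- out / (lf * af)
  oct_volume(out, volume$spacing * c(lf, 1, af), volume$metadata)
}

#' Persist / load an OCT volume (multi-page TIFF + JSON sidecar)
#'
#' The volume is stored as a float multi-page TIFF (one page per B-scan, page
#' rows = A-scans, page columns = depth, 64-bit samples so intensities
#' round-trip bit-exactly) together with a JSON sidecar `<path>.json` holding
#' `spacing_um` and the metadata.
#'
#' @param volume an [oct_volume()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `write_oct_volume` returns `path` invisibly; `read_oct_volume`
#'   returns the reconstructed `oct_volume`.
#' @export
write_oct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume)
  pages <- lapply(seq_len(d[1]), function(b) volume$intensity[b, , , drop = TRUE])
  if (d[2] == 1L || d[3] == 1L)
    pages <- lapply(pages, function(p) matrix(p, nrow = d[2], ncol = d[3]))
  write_float_tiff(pages, path, bits = 64L)
  sidecar <- paste0(path, ".json")
  payload <- c(list(spacing_um = as.numeric(volume$spacing)), volume$metadata)
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_oct_volume
#' @export
read_oct_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar for OCT volume; expected: ", sidecar)
  pages <- read_float_tiff(path)
  dims <- lapply(pages, dim)
  if (length(unique(dims)) != 1L)
    stop("TIFF page shapes differ; all B-scans must have identical dimensions")
  d <- dims[[1L]]
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (b in seq_along(pages)) arr[b, , ] <- pages[[b]]
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$spacing_um))
    stop("sidecar ", sidecar, " does not contain `spacing_um`")
  spacing <- as.numeric(meta$spacing_um)
  meta$spacing_um <- NULL
  oct_volume(arr, spacing, as.list(meta))
}
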