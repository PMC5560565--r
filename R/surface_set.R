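# Ordered axial surface sets.

.SURFACES_HEALTHY <- c("ILM", "RNFGC-IPL", "IPL-INL", "INL-OPL", "OPL-ONL",
                       "ELM", "EZ-Top", "EZ-Bottom", "OS-RPE", "BM")
.SURFACES_LD <- c("ILM", "RNFGC-IPL", "IPL-INL", "INL-OPL", "ONL-Top", "BM")

#' Canonical surface names in anatomical order
#'
#' Ten surfaces are segmented in healthy retinas and six in light-damage (LD)
#' retinas, where the photoreceptor layers may be absent and only the top of
#' the ONL and Bruch's membrane remain in the outer retina.
#'
#' @param mode `"healthy"` or `"ld"`.
#' @return character vector of surface names, vitreous side first.
#' @export
surface_names <- function(mode = c("healthy", "ld")) {
  mode <- match.arg(mode)
  if (mode == "healthy") .SURFACES_HEALTHY else .SURFACES_LD
}

#' Construct an ordered set of axial surfaces
#'
#' A surface set maps surface names to matrices `S(b, x)` of axial positions.
#' Surfaces must respect the anatomical ordering of the supplied list for
#' every column, with equality allowed so that a vanished layer may collapse
#' to zero thickness.
#'
#' @param surfaces named list of numeric `B x X` matrices of axial positions
#'   (0-based voxel units unless `units = "um"`), ordered inner to outer.
#' @param units `"voxel"` or `"um"`.
#' @param resolution free-form tag, conventionally `"native"` or
#'   `"downsampled"`.
#' @param check validate ordering and finiteness (disable only for trusted
#'   internal callers).
#' @return an object of class `surface_set`.
#' @export
surface_set <- function(surfaces, units = c("voxel", "um"),
                        resolution = "native", check = TRUE) {
  units <- match.arg(units)
  if (!is.list(surfaces) || is.null(names(surfaces)) || any(names(surfaces) == ""))
    stop("`surfaces` must be a named list of matrices")
  surfaces <- lapply(surfaces, function(s) {
    if (is.vector(s)) s <- matrix(s, nrow = 1L)
    s
  })
  d <- dim(surfaces[[1L]])
  if (check) {
    for (nm in names(surfaces)) {
      s <- surfaces[[nm]]
      if (!is.matrix(s) || !identical(dim(s), d))
        stop("surface `", nm, "` does not match the grid of the first surface")
      if (anyNA(s) || any(!is.finite(s))) stop("surface `", nm, "` has non-finite values")
      if (any(s < 0)) stop("surface `", nm, "` has negative axial positions")
    }
    if (length(surfaces) > 1L) {
      for (i in seq_len(length(surfaces) - 1L)) {
        if (any(surfaces[[i + 1L]] - surfaces[[i]] < -1e-9))
          stop("surfaces `", names(surfaces)[i], "` and `", names(surfaces)[i + 1L],
               "` violate the anatomical ordering")
      }
    }
  }
  structure(
    list(surfaces = surfaces, units = units, resolution = resolution),
    class = "surface_set"
  )
}

#' @export
print.surface_set <- function(x, ...) {
  d <- dim(x$surfaces[[1L]])
  cat(sprintf("<surface_set> %d surfaces on a %d x %d (b, x) grid [%s, %s]\n",
              length(x$surfaces), d[1], d[2], x$units, x$resolution))
  rng <- vapply(x$surfaces, range, numeric(2))
  for (nm in names(x$surfaces))
    cat(sprintf("  %-10s z in [%.2f, %.2f]\n", nm, rng[1, nm], rng[2, nm]))
  invisible(x)
}

#' @export
names.surface_set <- function(x) names(x$surfaces)

#' @export
`[[.surface_set` <- function(x, i) x$surfaces[[i]]

#' Rescale surfaces from a downsampled grid back to native resolution
#'
#' The lateral grid is densified by linear interpolation: downsampled column
#' `j` (0-based) maps to native column `j * lateral_factor`, intermediate
#' native columns are linearly interpolated and columns beyond the last
#' mapped one take its value (constant edge extension). Axial positions are
#' multiplied by `axial_factor`.
#'
#' @param surfaces a [surface_set()] at downsampled resolution.
#' @param lateral_factor,axial_factor integer factors `>= 1`.
#' @param x_out number of native lateral columns (defaults to
#'   `X * lateral_factor`).
#' @return a `surface_set` tagged `"native"`.
#' @export
rescale_surfaces <- function(surfaces, lateral_factor = 2L, axial_factor = 2L,
                             x_out = NULL) {
  stopifnot(inherits(surfaces, "surface_set"))
  lf <- as.integer(lateral_factor); af <- as.integer(axial_factor)
  if (lf < 1L || af < 1L) stop("rescaling factors must be integers >= 1")
  d <- dim(surfaces$surfaces[[1L]])
  if (is.null(x_out)) x_out <- d[2] * lf
  if (lf == 1L && af == 1L && x_out == d[2]) {
    out <- lapply(surfaces$surfaces, identity)
  } else {
    x_src <- (seq_len(d[2]) - 1L) * lf
    x_tgt <- seq_len(x_out) - 1L
    out <- lapply(surfaces$surfaces, function(s) {
      r <- matrix(0, d[1], x_out)
      for (b in seq_len(d[1])) {
        if (d[2] == 1L) {
          r[b, ] <- s[b, 1L] * af
        } else {
          r[b, ] <- stats::approx(x_src, s[b, ] * af, xout = x_tgt, rule = 2)$y
        }
      }
      r
    })
  }
  surface_set(out, units = surfaces$units, resolution = "native")
}

#' Persist / load a surface set (float TIFF + JSON sidecar)
#'
#' One 32-bit float page per surface (values are axial positions in voxels),
#' plus a JSON sidecar `<path>.json` listing the surface names in anatomical
#' order together with the units and resolution tags.
#'
#' @param surfaces a [surface_set()].
#' @param path TIFF file path.
#' @return `write_surface_set` returns `path` invisibly; `read_surface_set`
#'   the reconstructed `surface_set`.
#' @export
write_surface_set <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "surface_set"))
  write_float_tiff(unname(surfaces$surfaces), path, bits = 32L)
  jsonlite::write_json(
    list(surfaces = names(surfaces$surfaces), units = surfaces$units,
         resolution = surfaces$resolution),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface_set
#' @export
read_surface_set <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar for surface set; expected: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- read_float_tiff(path)
  if (length(pages) != length(meta$surfaces))
    stop("TIFF page count does not match the sidecar surface list")
  names(pages) <- meta$surfaces
  surface_set(pages, units = meta$units, resolution = meta$resolution)
}
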