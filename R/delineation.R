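# Sparse manual delineations: control points joined by an interpolating
# spline, the tracing protocol used for training labels and validation.

#' Construct a manual delineation
#'
#' A delineation records, per traced (surface, B-scan) pair, the control
#' points a rater placed along the surface. Control points are joined by an
#' interpolating spline when the delineation is evaluated on a lateral grid.
#'
#' @param rater rater identifier (character).
#' @param slices list of slice tracings, each a list with elements `b`
#'   (0-based B-scan index), `surface` (name), and `points` (n x 2 matrix of
#'   `(x, z)` positions, 0-based voxel units, `x` strictly increasing,
#'   `n >= 2`).
#' @param rule interpolation rule: `"natural"` (natural cubic spline,
#'   default), `"cubic"` (cubic spline with Forsythe-Malcolm-Moler end
#'   conditions, exact on data sampled from a single cubic polynomial), or
#'   `"linear"`.
#' @param repeat_id identifier distinguishing repeat tracings of the same
#'   content by the same rater (`NA` for the primary tracing).
#' @return an object of class `delineation`.
#' @export
delineation <- function(rater, slices, rule = c("natural", "cubic", "linear"),
                        repeat_id = NA_character_) {
  rule <- match.arg(rule)
  if (!is.list(slices)) stop("`slices` must be a list")
  for (sl in slices) {
    if (!all(c("b", "surface", "points") %in% names(sl)))
      stop("each slice needs elements `b`, `surface`, `points`")
    p <- sl$points
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 2L)
      stop("each traced surface needs at least 2 control points (n x 2 matrix)")
    if (any(diff(p[, 1L]) <= 0))
      stop("control point x positions must be strictly increasing")
  }
  structure(
    list(rater = as.character(rater), slices = slices, rule = rule,
         repeat_id = repeat_id),
    class = "delineation"
  )
}

#' @export
print.delineation <- function(x, ...) {
  cat(sprintf("<delineation> rater %s%s: %d traced (surface, slice) pairs [%s]\n",
              x$rater,
              if (is.na(x$repeat_id)) "" else paste0(" (repeat ", x$repeat_id, ")"),
              length(x$slices), x$rule))
  invisible(x)
}

.interp_points <- function(points, x_grid, rule) {
  x <- points[, 1L]; z <- points[, 2L]
  y <- switch(rule,
    natural = stats::spline(x, z, xout = x_grid, method = "natural")$y,
    cubic = stats::spline(x, z, xout = x_grid, method = "fmm")$y,
    linear = stats::approx(x, z, xout = x_grid, rule = 1)$y
  )
  y[x_grid < min(x) | x_grid > max(x)] <- NA_real_  # never extrapolate
  y
}

#' Evaluate a delineation on a lateral grid
#'
#' Each traced (surface, B-scan) pair is interpolated at the requested lateral
#' positions with the delineation's spline rule. Positions outside the control
#' point span are returned as `NA` (missing), never extrapolated.
#'
#' @param delin a [delineation()].
#' @param x_grid numeric vector of lateral positions (0-based voxel units).
#' @return nested list: `result[[surface]][[as.character(b)]]` is a numeric
#'   vector over `x_grid` with `NA` outside the traced span.
#' @export
delineation_to_surface <- function(delin, x_grid) {
  stopifnot(inherits(delin, "delineation"))
  out <- list()
  for (sl in delin$slices) {
    key <- as.character(sl$b)
    out[[sl$surface]][[key]] <- .interp_points(sl$points, x_grid, delin$rule)
  }
  out
}

#' Persist / load delineations as JSON
#'
#' @param delin a [delineation()].
#' @param path JSON file path.
#' @return `write_delineation` returns `path` invisibly; `read_delineation`
#'   the reconstructed `delineation`.
#' @export
write_delineation <- function(delin, path) {
  stopifnot(inherits(delin, "delineation"))
  payload <- list(
    rater = delin$rater, rule = delin$rule,
    repeat_id = if (is.na(delin$repeat_id)) NULL else delin$repeat_id,
    slices = lapply(delin$slices, function(sl)
      list(b = sl$b, surface = sl$surface,
           points = lapply(seq_len(nrow(sl$points)),
                           function(i) as.numeric(sl$points[i, ]))))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_delineation
#' @export
read_delineation <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  slices <- lapply(p$slices, function(sl) {
    pts <- do.call(rbind, lapply(sl$points, function(q) as.numeric(unlist(q))))
    list(b = as.integer(sl$b), surface = sl$surface, points = pts)
  })
  delineation(p$rater, slices, rule = p$rule,
              repeat_id = if (is.null(p$repeat_id)) NA_character_ else p$repeat_id)
}
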