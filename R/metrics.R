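# Validation machinery: annular evaluation masks, unsigned border position
# error, and intra/inter-rater variability tables.

#' Annular evaluation mask over the en-face (b, x) grid
#'
#' Scans are centred on the optic nerve head, where layers are ill-defined;
#' a 0.3 mm-diameter central disc is excluded, as is the periphery beyond a
#' 1.2 mm-diameter circle. Membership is decided by the annulus inequality
#' `d_inner/2 <= r <= d_outer/2` with boundary pixels included at both
#' radii, computed with the anisotropic pixel spacing.
#'
#' @param shape `(B, X)` grid size (a volume's first two dimensions).
#' @param spacing voxel spacing in um; the first two components `(x, y)`
#'   are used.
#' @param center en-face centre `(b, x)` in 0-based pixel units (defaults
#'   to the grid centre).
#' @param d_inner_mm,d_outer_mm excluded-disc and inclusion-circle
#'   diameters (mm); `d_inner_mm < d_outer_mm` required.
#' @return logical `B x X` matrix of class `eval_mask` with the geometry
#'   stored in attributes.
#' @export
make_eval_mask <- function(shape, spacing, center = NULL,
                           d_inner_mm = 0.3, d_outer_mm = 1.2) {
  if (d_inner_mm >= d_outer_mm) stop("d_inner_mm must be < d_outer_mm")
  B <- shape[1]; X <- shape[2]
  if (is.null(center)) center <- c((B - 1) / 2, (X - 1) / 2)
  bb <- matrix(seq_len(B) - 1 - center[1], B, X)
  xx <- matrix(seq_len(X) - 1 - center[2], B, X, byrow = TRUE)
  r_mm <- sqrt((bb * spacing[2])^2 + (xx * spacing[1])^2) / 1000
  eps <- 1e-9
  m <- r_mm >= d_inner_mm / 2 - eps & r_mm <= d_outer_mm / 2 + eps
  structure(m, class = c("eval_mask", "matrix"),
            center = center, spacing = spacing[1:2],
            d_inner_mm = d_inner_mm, d_outer_mm = d_outer_mm)
}

#' Unsigned border position error between two surfaces
#'
#' Mean and SD of `|a - b| * axial_spacing` over the masked columns, the
#' dissimilarity measure used both between raters and between automated and
#' manual tracings. Columns where either surface is missing (`NA`) are
#' excluded pairwise.
#'
#' @param a,b numeric matrices (or vectors) of axial positions on the same
#'   grid, in voxels.
#' @param mask optional logical mask selecting columns; default all.
#' @param axial_spacing axial voxel size in um (1 = report in voxels).
#' @return named numeric vector `c(mean, sd, n)` (mean/SD in um).
#' @export
border_error <- function(a, b, mask = NULL, axial_spacing = 1) {
  if (length(a) != length(b)) stop("surfaces must share a grid")
  sel <- !is.na(a) & !is.na(b)
  if (!is.null(mask)) sel <- sel & as.logical(mask)
  if (!any(sel)) stop("no valid columns under the evaluation mask")
  d <- abs(a[sel] - b[sel]) * axial_spacing
  c(mean = mean(d), sd = if (length(d) > 1L) stats::sd(d) else 0, n = length(d))
}

# per-slice mean unsigned differences between two delineation evaluations
.pair_slice_errors <- function(eval_a, eval_b, mask, sz, bm_surrogate = FALSE) {
  out <- list()
  surfaces <- union(names(eval_a), names(eval_b))
  for (nm in surfaces) {
    for (b in names(eval_a[[nm]] %||% list())) {
      za <- eval_a[[nm]][[b]]
      zb <- eval_b[[nm]][[b]]
      if (is.null(zb) && bm_surrogate && nm == "ONL-Top")
        zb <- eval_b[["BM"]][[b]]
      if (is.null(zb)) next
      row <- as.integer(b) + 1L
      ok <- tryCatch(border_error(za, zb, mask[row, ], sz),
                     error = function(e) NULL)
      if (is.null(ok)) next
      out[[length(out) + 1L]] <- data.frame(surface = nm, b = as.integer(b),
                                            mean_um = ok[["mean"]],
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

.summarize_slices <- function(df, extra) {
  agg <- lapply(split(df, df$surface), function(g)
    cbind(extra, data.frame(surface = g$surface[1], n_slices = nrow(g),
                            mean_um = mean(g$mean_um),
                            sd_um = if (nrow(g) > 1L) stats::sd(g$mean_um) else NA_real_,
                            stringsAsFactors = FALSE)))
  do.call(rbind, agg)
}

#' Intra-rater, inter-rater and automated-vs-rater variability tables
#'
#' Per-slice mean unsigned border differences are aggregated per surface as
#' mean +/- SD across slices. Intra-rater rows compare repeat tracings by
#' the same rater; inter-rater rows compare the primary tracings of each
#' rater pair; automated rows compare an automated surface set against each
#' rater. Where the top of the ONL was not traced on a slice, Bruch's
#' membrane is used as its surrogate in the automated comparison.
#'
#' @param delineations list of [delineation()]s (native voxel units).
#' @param surfaces_auto optional native-resolution [surface_set()] from the
#'   automated segmentation.
#' @param mask an [make_eval_mask()] (or logical `B x X` matrix).
#' @param spacing volume voxel spacing in um (`z` component used).
#' @param x_grid lateral evaluation grid (default all columns of `mask`).
#' @return list of data frames `intra`, `inter`, `auto`.
#' @export
variability_tables <- function(delineations, surfaces_auto = NULL, mask,
                               spacing, x_grid = NULL) {
  sz <- spacing[3]
  X <- ncol(mask)
  if (is.null(x_grid)) x_grid <- 0:(X - 1)
  evals <- lapply(delineations, delineation_to_surface, x_grid = x_grid)
  raters <- vapply(delineations, function(d) d$rater, "")
  repeats <- vapply(delineations, function(d)
    if (is.na(d$repeat_id)) NA_character_ else d$repeat_id, "")

  intra <- list()
  for (r in unique(raters)) {
    ix <- which(raters == r)
    if (length(ix) < 2L) next
    for (i in seq_along(ix)) for (j in seq_along(ix)) {
      if (i >= j) next
      df <- .pair_slice_errors(evals[[ix[i]]], evals[[ix[j]]], mask, sz)
      if (!is.null(df))
        intra[[length(intra) + 1L]] <-
          .summarize_slices(df, data.frame(rater = r, stringsAsFactors = FALSE))
    }
  }
  if (!length(intra))
    warning("no repeat tracings found; intra-rater table is empty")

  inter <- list()
  prim <- which(is.na(repeats))
  prim <- prim[!duplicated(raters[prim])]
  if (length(prim) >= 2L) {
    for (i in seq_along(prim)) for (j in seq_along(prim)) {
      if (i >= j) next
      a <- prim[i]; b <- prim[j]
      df <- .pair_slice_errors(evals[[a]], evals[[b]], mask, sz)
      if (!is.null(df))
        inter[[length(inter) + 1L]] <- .summarize_slices(
          df, data.frame(pair = paste(raters[a], "vs", raters[b]),
                         stringsAsFactors = FALSE))
    }
  }

  auto <- list()
  if (!is.null(surfaces_auto)) {
    for (k in prim) {
      ev <- evals[[k]]
      # automated surfaces evaluated on the rater's traced slices
      auto_eval <- list()
      for (nm in names(surfaces_auto$surfaces)) {
        for (b in unique(unlist(lapply(ev, names)))) {
          auto_eval[[nm]][[b]] <-
            surfaces_auto$surfaces[[nm]][as.integer(b) + 1L, x_grid + 1L]
        }
      }
      df <- .pair_slice_errors(auto_eval, ev, mask, sz, bm_surrogate = TRUE)
      if (!is.null(df))
        auto[[length(auto) + 1L]] <- .summarize_slices(
          df, data.frame(pair = paste("auto vs", raters[k]),
                         stringsAsFactors = FALSE))
    }
  }

  bindf <- function(l) if (length(l)) { o <- do.call(rbind, l); rownames(o) <- NULL; o } else NULL
  list(intra = bindf(intra), inter = bindf(inter), auto = bindf(auto))
}
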