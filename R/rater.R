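# Simulated human raters: noisy control-point tracings of phantom truth,
# used for classifier training labels and for intra/inter-rater
# variability experiments.

#' A simulated rater's behaviour
#'
#' @param bias_um systematic axial offset of placed control points (um).
#' @param sd_um SD of the independent axial placement noise (um). A value
#'   near 1 um reproduces the magnitude of typical intra-rater variability
#'   for these scans (about 1.3 um mean unsigned difference between
#'   repeats).
#' @param spacing_px lateral spacing between successive control points
#'   (voxels).
#' @param vessel_behavior `"through"` (trace straight through vessel
#'   shadows) or `"around"` (displace control points upward inside shadows,
#'   a behaviour observed in real raters on the lower RNFGC boundary).
#' @param vessel_offset_um upward displacement used by `"around"` raters.
#' @return an object of class `rater_model`.
#' @export
rater_model <- function(bias_um = 0, sd_um = 1.0, spacing_px = 15L,
                        vessel_behavior = c("through", "around"),
                        vessel_offset_um = 3) {
  vessel_behavior <- match.arg(vessel_behavior)
  if (sd_um < 0) stop("rater noise SD must be >= 0")
  structure(list(bias_um = bias_um, sd_um = sd_um,
                 spacing_px = as.integer(spacing_px),
                 vessel_behavior = vessel_behavior,
                 vessel_offset_um = vessel_offset_um),
            class = "rater_model")
}

#' Simulate a manual delineation of phantom truth
#'
#' Control points are the truth surfaces sampled at the rater's lateral
#' spacing plus independent `N(bias, sd^2)` axial noise (in um, converted to
#' voxels). Deterministic given the seed; a repeat tracing with a different
#' seed yields an independent noise draw, supporting intra-rater
#' experiments.
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param rater a [rater_model()].
#' @param slice_ids 0-based B-scan indices to trace (non-empty).
#' @param seed integer seed.
#' @param surfaces surface names to trace (default: all truth surfaces).
#' @param repeat_id optional repeat tag for intra-rater experiments.
#' @param rater_id rater name recorded in the delineation.
#' @return a [delineation()] in native voxel units.
#' @export
simulate_rater <- function(truth, rater, slice_ids, seed = 1L,
                           surfaces = names(truth$surfaces$surfaces),
                           repeat_id = NA_character_, rater_id = "sim") {
  stopifnot(inherits(truth, "phantom_truth"), inherits(rater, "rater_model"))
  if (!length(slice_ids)) stop("`slice_ids` must name at least one B-scan")
  d <- dim(truth$surfaces$surfaces[[1L]])
  if (any(slice_ids < 0 | slice_ids > d[1] - 1L))
    stop("slice ids outside the volume")
  sz <- truth$params$spacing[3]
  xs <- unique(c(seq(0L, d[2] - 1L, by = max(1L, rater$spacing_px)), d[2] - 1L))
  vx <- truth$realized$vessel_centers
  with_seed(seed, {
    slices <- list()
    for (b in slice_ids) {
      for (nm in surfaces) {
        s <- truth$surfaces$surfaces[[nm]]
        z <- s[b + 1L, xs + 1L] +
          stats::rnorm(length(xs), rater$bias_um, rater$sd_um) / sz
        if (rater$vessel_behavior == "around" && nm != "ILM" && length(vx)) {
          inshadow <- vapply(xs, function(x)
            any(abs(x + 1L - vx) <= truth$params$vessel_width_px / 2), logical(1))
          z[inshadow] <- z[inshadow] - rater$vessel_offset_um / sz
        }
        z <- .clamp(z, 0, truth$params$shape[3] - 1)
        slices[[length(slices) + 1L]] <-
          list(b = as.integer(b), surface = nm, points = cbind(xs, z))
      }
    }
    delineation(rater_id, slices, rule = "natural", repeat_id = repeat_id)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
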