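# The three-stage segmentation pipeline: work at half resolution, localize
# a coarse ROI at quarter resolution with gradient costs, then segment the
# surface groups in three constrained min-cut stages and rescale the result
# to native resolution.

# Expected separation range (um) between two surfaces, from the nominal
# layer thicknesses +/- the fractional tolerance. In LD mode the ablatable
# outer bands contribute zero to the lower bound, since the outer retina
# may vanish entirely.
.sep_bounds_um <- function(mode, upper, lower, tol) {
  layers <- if (mode == "healthy") .LAYERS_HEALTHY else .LAYERS_LD
  bands <- c("ILM", "RNFGC-IPL", "IPL-INL", "INL-OPL", "OPL-ONL",
             "ELM", "EZ-Top", "EZ-Bottom", "OS-RPE", "BM")
  # band i spans surfaces i..i+1 and corresponds to layers$thickness_um[i]
  iu <- match(if (upper == "ONL-Top") "OPL-ONL" else upper, bands)
  il <- match(if (lower == "ONL-Top") "OPL-ONL" else lower, bands)
  if (iu == il) return(c(lo = 0, hi = 0))
  th <- layers$thickness_um[iu:(il - 1)]
  th_lo <- th
  if (mode == "ld")
    th_lo[layers$layer[iu:(il - 1)] %in% .LD_ABLATED] <- 0
  c(lo = (1 - tol) * sum(th_lo), hi = (1 + tol) * sum(th))
}

#' Stage plan of the segmentation pipeline
#'
#' Surfaces are segmented in three simultaneous groups: the RNFGC complex
#' bounds first, then the remaining inner retinal surfaces (for
#' light-damage scans only the INL bounds, as the lower OPL boundary is not
#' reliably visible), and finally the outer retinal surfaces (for
#' light-damage scans only the ONL top and Bruch's membrane, with the
#' minimum ONL thickness set to zero so the two may coincide).
#'
#' @param mode `"healthy"` or `"ld"`.
#' @return list of character vectors of surface names, one per stage.
#' @export
stage_plan <- function(mode = c("healthy", "ld")) {
  mode <- match.arg(mode)
  if (mode == "healthy") {
    list(stage1 = c("ILM", "RNFGC-IPL"),
         stage2 = c("IPL-INL", "INL-OPL", "OPL-ONL"),
         stage3 = c("ELM", "EZ-Top", "EZ-Bottom", "OS-RPE", "BM"))
  } else {
    list(stage1 = c("ILM", "RNFGC-IPL"),
         stage2 = c("IPL-INL", "INL-OPL"),
         stage3 = c("ONL-Top", "BM"))
  }
}

#' Pipeline configuration
#'
#' Constraint values are fixed expected parameters: smoothness defaults of
#' 2 voxels laterally and a relaxed 6 voxels between B-scans (absorbing
#' axial motion), and per-pair separations derived from nominal layer
#' thicknesses +/- 50%. All are expressed at the working (half) resolution
#' and exposed here.
#'
#' @param mode `"healthy"` or `"ld"`.
#' @param lateral_factor,axial_factor native-to-working downsampling
#'   factors.
#' @param coarse_factor additional downsampling for ROI localization.
#' @param margin_voxels ROI margin above/below the coarse surfaces
#'   (working-resolution voxels).
#' @param guard_voxels guard band subtracted from the previous stage's
#'   minimum depth when restricting the next stage.
#' @param smooth_x,smooth_b smoothness bounds (working voxels).
#' @param sep_tolerance fractional tolerance around nominal separations.
#' @param gradient_scale axial Gaussian scale of the gradient costs.
#' @param coarse_scale axial Gaussian scale used at the quarter-resolution
#'   coarse stage, where the hyperreflective RNFGC band is only about two
#'   voxels thick and a large kernel would displace the apparent edge.
#' @param collapse_prior cost per voxel of separation applied to surface
#'   pairs whose minimum separation is zero (a layer that may vanish, such
#'   as the LD-mode ONL). Acts as a collapse prior: where the two
#'   boundaries are the same image edge and the classifier evidence is
#'   ambiguous, the pair is pinched to exact coincidence; where a real
#'   layer remains, the boundary evidence (an order of magnitude larger per
#'   voxel) dominates.
#' @param collapse_snap_voxels visibility threshold for vanishable pairs
#'   (working-resolution voxels): after the stage solve, columns whose
#'   separation is at or below this are treated as having no visible layer
#'   and the upper surface collapses onto the lower one (the top of the ONL
#'   onto Bruch's membrane). Separations this small are below the
#'   resolution of the boundary cost model, so they indicate noise, not a
#'   resolved layer. Set to 0 to disable.
#' @return a named list of class `seg_config`.
#' @export
seg_config <- function(mode = c("healthy", "ld"), lateral_factor = 2L,
                       axial_factor = 2L, coarse_factor = 4L,
                       margin_voxels = 10L, guard_voxels = 2L,
                       smooth_x = 2, smooth_b = 6, sep_tolerance = 0.5,
                       gradient_scale = 1.5, coarse_scale = 0.8,
                       collapse_prior = 0.05, collapse_snap_voxels = 3) {
  mode <- match.arg(mode)
  structure(list(mode = mode, lateral_factor = as.integer(lateral_factor),
                 axial_factor = as.integer(axial_factor),
                 coarse_factor = as.integer(coarse_factor),
                 margin_voxels = as.integer(margin_voxels),
                 guard_voxels = as.integer(guard_voxels),
                 smooth_x = smooth_x, smooth_b = smooth_b,
                 sep_tolerance = sep_tolerance,
                 gradient_scale = gradient_scale, coarse_scale = coarse_scale,
                 collapse_prior = collapse_prior,
                 collapse_snap_voxels = collapse_snap_voxels),
            class = "seg_config")
}

# separation constraints for a stage, in working-resolution voxels
.stage_constraints <- function(stage_surfaces, mode, config, axial_um) {
  ns <- length(stage_surfaces)
  if (ns == 1L)
    return(constraint_spec(config$smooth_x, config$smooth_b, n_surfaces = 1L))
  bounds <- vapply(seq_len(ns - 1L), function(i)
    .sep_bounds_um(mode, stage_surfaces[i], stage_surfaces[i + 1L],
                   config$sep_tolerance), numeric(2))
  min_sep <- floor(bounds["lo", ] / axial_um)
  max_sep <- ceiling(bounds["hi", ] / axial_um)
  constraint_spec(config$smooth_x, config$smooth_b, min_sep, max_sep,
                  n_surfaces = ns)
}

# per-mode gradient polarities of each surface (phantom contrast ordering)
.GRADIENT_POLARITY <- c(
  "ILM" = "dark_to_bright", "RNFGC-IPL" = "bright_to_dark",
  "IPL-INL" = "bright_to_dark", "INL-OPL" = "dark_to_bright",
  "OPL-ONL" = "bright_to_dark", "ELM" = "dark_to_bright",
  "EZ-Top" = "dark_to_bright", "EZ-Bottom" = "bright_to_dark",
  "OS-RPE" = "dark_to_bright", "BM" = "bright_to_dark",
  "ONL-Top" = "bright_to_dark"
)

#' Coarse region-of-interest localization
#'
#' The working-resolution volume is downsampled by a further factor
#' (default 4, lateral and axial), the ILM and a deep outer boundary are
#' segmented simultaneously with gradient costs (dark-to-bright for the
#' ILM, the deepest strong bright-to-dark transition for the
#' retina/choroid boundary), and the two surfaces are rescaled back to the
#' working grid. All subsequent processing is limited to the resulting
#' depth band `[min(ILM) - margin, max(bottom) + margin]`.
#'
#' @param volume working-resolution [oct_volume()].
#' @param config a [seg_config()].
#' @return list with `ilm`, `bottom` (`B x X` matrices, working voxels),
#'   `zmin`, `zmax` (0-based band bounds).
#' @export
coarse_localize <- function(volume, config = seg_config()) {
  stopifnot(inherits(volume, "oct_volume"))
  cf <- config$coarse_factor
  v4 <- downsample_volume(volume, cf, cf)
  axial4_um <- v4$spacing[3]
  mode <- config$mode
  layers <- if (mode == "healthy") .LAYERS_HEALTHY else .LAYERS_LD
  trt_um <- sum(layers$thickness_um)
  # in LD scans the outer bands may be fully ablated, so the minimum
  # retina span is the inner stack alone
  trt_lo <- if (mode == "ld")
    sum(layers$thickness_um[!layers$layer %in% .LD_ABLATED]) else trt_um
  min_sep <- max(1, floor(0.5 * min(trt_um, trt_lo) / axial4_um))
  max_sep <- ceiling(1.5 * trt_um / axial4_um)
  cons <- constraint_spec(smooth_x = 2, smooth_b = 3,
                          min_sep = min_sep, max_sep = max_sep,
                          n_surfaces = 2L)
  c_ilm <- gradient_cost(v4, "dark_to_bright", scale = config$coarse_scale)
  c_bot <- gradient_cost(v4, "bright_to_dark", scale = config$coarse_scale)
  ss <- segment_surfaces(list(c_ilm, c_bot), cons, names = c("ILM", "bottom"))
  # parabolic sub-voxel refinement around the solved minimum: the coarse
  # grid quantizes to cf working voxels, too crude for the downstream
  # anchors without it
  refine <- function(surf, cost) {
    d <- dim(cost); Z4 <- d[3]
    z <- surf
    zc <- pmin(pmax(z, 1), Z4 - 2)  # need both neighbours
    idx <- cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]))
    cm <- cost[cbind(idx, as.vector(zc) + 0L)]
    c0 <- cost[cbind(idx, as.vector(zc) + 1L)]
    cp <- cost[cbind(idx, as.vector(zc) + 2L)]
    den <- cm - 2 * c0 + cp
    delta <- ifelse(den > 1e-12, 0.5 * (cm - cp) / den, 0)
    surf + matrix(pmin(pmax(delta, -0.5), 0.5), d[1], d[2])
  }
  ss$surfaces$ILM <- refine(ss$surfaces$ILM, c_ilm)
  ss$surfaces$bottom <- refine(ss$surfaces$bottom, c_bot)
  ss_w <- rescale_surfaces(ss, cf, cf, x_out = dim(volume)[2])
  # block-centre phase: coarse voxel c spans working [cf*c, cf*c + cf - 1]
  phase <- (cf - 1) / 2
  ilm <- ss_w$surfaces$ILM + phase
  bottom <- ss_w$surfaces$bottom + phase
  Z <- dim(volume)[3]
  zmin <- max(0L, floor(min(ilm)) - config$margin_voxels)
  zmax <- min(Z - 1L, ceiling(max(bottom)) + config$margin_voxels)
  list(ilm = ilm, bottom = bottom,
       zmin = as.integer(zmin), zmax = as.integer(zmax))
}

#' Run the full three-stage segmentation pipeline
#'
#' The native volume is downsampled by two laterally and axially (the
#' number of B-scans is unchanged), a coarse ROI is localized, the three
#' stages are solved as constrained min-cut problems restricted to lie at
#' or below the previous stage (minus a small guard band), per-column
#' ordering is enforced across stage boundaries, and all surfaces are
#' rescaled to native resolution. Healthy mode yields 10 surfaces, LD mode
#' 6, with the ONL top allowed to coincide with Bruch's membrane.
#'
#' @param volume native-resolution [oct_volume()].
#' @param mode `"healthy"` or `"ld"`.
#' @param models named list of [train_boundary_classifier()] models
#'   (`stage1`..`stage3`) for the stages using `"model"` costs; may be
#'   `NULL` if all stages use gradient costs.
#' @param config a [seg_config()] (defaults to `seg_config(mode)`).
#' @param cost_source `"model"` or `"gradient"`, recycled per stage.
#' @return an object of class `oct_segmentation`: native-resolution
#'   surfaces, the working-resolution surfaces, ROI, timings and
#'   configuration.
#' @export
segment_retina <- function(volume, mode = c("healthy", "ld"), models = NULL,
                           config = NULL, cost_source = "model") {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "oct_volume"))
  if (is.null(config)) config <- seg_config(mode)
  if (config$mode != mode) stop("config was built for mode ", config$mode)
  plan <- stage_plan(mode)
  cost_source <- rep_len(cost_source, length(plan))
  if (any(cost_source == "model")) {
    need <- names(plan)[cost_source == "model"]
    if (is.null(models) || !all(need %in% names(models)))
      stop("models required for stage(s): ", paste(need, collapse = ", "))
    for (nm in need) {
      m <- models[[nm]]
      if (!inherits(m, "boundary_model"))
        stop("`models$", nm, "` is not a boundary_model")
      if (m$mode != mode)
        stop("model for ", nm, " was trained for mode ", m$mode,
             "; control and LD scans use separate classifiers")
      if (!setequal(m$stage_surfaces, plan[[nm]]))
        stop("model for ", nm, " segments surfaces ",
             paste(m$stage_surfaces, collapse = ", "),
             " but the plan requires ", paste(plan[[nm]], collapse = ", "))
    }
  }

  timings <- c()
  tic <- function() proc.time()[[3]]
  t0 <- tic()
  vws <- downsample_volume(volume, config$lateral_factor, config$axial_factor)
  axial_ws_um <- vws$spacing[3]
  timings["downsample"] <- tic() - t0

  t0 <- tic()
  roi <- coarse_localize(vws, config)
  timings["coarse"] <- tic() - t0

  stack <- NULL
  if (any(cost_source == "model")) {
    t0 <- tic()
    stack <- extract_features(vws, roi)
    timings["features"] <- tic() - t0
  }

  surfaces_ws <- list()
  prev_bottom <- NULL
  for (k in seq_along(plan)) {
    t0 <- tic()
    snames <- plan[[k]]
    if (cost_source[k] == "model") {
      costs_band <- predict_costs(models[[names(plan)[k]]], stack)
    } else {
      zidx <- (roi$zmin:roi$zmax) + 1L
      costs_band <- lapply(snames, function(nm)
        gradient_cost(vws, .GRADIENT_POLARITY[[nm]],
                      scale = config$gradient_scale)[, , zidx, drop = FALSE])
      names(costs_band) <- snames
    }
    nz <- roi$zmax - roi$zmin + 1L
    zmin_s <- rep(0L, length(snames)); zmax_s <- rep(nz - 1L, length(snames))
    # anchor each stage surface to its expected separation range from the
    # anchor surface: the coarse ILM estimate for stage 1 (slack = the ROI
    # margin, absorbing coarse-localization error), the previous stage's
    # lowest surface afterwards (slack = the guard band)
    if (k == 1L) {
      anchor <- roi$ilm; anchor_name <- "ILM"; slack <- config$margin_voxels
    } else {
      anchor <- prev_bottom
      anchor_name <- plan[[k - 1L]][length(plan[[k - 1L]])]
      slack <- config$guard_voxels
    }
    for (j in seq_along(snames)) {
      sb <- .sep_bounds_um(mode, anchor_name, snames[j], config$sep_tolerance)
      zmin_s[j] <- max(0L, floor(min(anchor) + sb[["lo"]] / axial_ws_um) -
                         slack - roi$zmin)
      zmax_s[j] <- min(nz - 1L,
                       ceiling(max(anchor) + sb[["hi"]] / axial_ws_um) +
                         slack - roi$zmin)
    }
    cons <- .stage_constraints(snames, mode, config, axial_ws_um)
    if (config$collapse_prior > 0 && length(snames) > 1L) {
      # linear separation penalty eps * (S_lower - S_upper) for vanishable
      # pairs, realized by sloping the two cost volumes in opposite senses
      zslope <- array(rep(0:(dim(costs_band[[1L]])[3] - 1L),
                          each = prod(dim(costs_band[[1L]])[1:2])),
                      dim(costs_band[[1L]])) * config$collapse_prior
      for (i in which(cons$min_sep == 0)) {
        costs_band[[i]] <- costs_band[[i]] - zslope
        costs_band[[i + 1L]] <- costs_band[[i + 1L]] + zslope
      }
    }
    ss <- segment_surfaces(costs_band, cons, names = snames,
                           zmin = zmin_s, zmax = zmax_s)
    if (config$collapse_snap_voxels > 0) {
      for (i in which(cons$min_sep == 0)) {
        gap <- ss$surfaces[[i + 1L]] - ss$surfaces[[i]]
        snap <- gap <= config$collapse_snap_voxels
        ss$surfaces[[i]][snap] <- ss$surfaces[[i + 1L]][snap]
      }
    }
    for (nm in snames) {
      s <- ss$surfaces[[nm]] + roi$zmin
      if (!is.null(prev_bottom)) s <- pmax(s, prev_bottom)
      surfaces_ws[[nm]] <- s
    }
    prev_bottom <- surfaces_ws[[snames[length(snames)]]]
    timings[names(plan)[k]] <- tic() - t0
  }

  ss_ws <- surface_set(surfaces_ws, units = "voxel", resolution = "working")
  ss_native <- rescale_surfaces(ss_ws, config$lateral_factor,
                                config$axial_factor, x_out = dim(volume)[2])
  structure(list(
    surfaces = ss_native, surfaces_working = ss_ws, roi = roi, mode = mode,
    config = config, timings = timings, spacing = volume$spacing,
    dim = dim(volume)
  ), class = "oct_segmentation")
}

#' @export
print.oct_segmentation <- function(x, ...) {
  cat(sprintf("<oct_segmentation> mode %s: %d surfaces on a %d x %d grid\n",
              x$mode, length(x$surfaces$surfaces), x$dim[1], x$dim[2]))
  cat(sprintf("  total time %.1f s (%s)\n", sum(x$timings),
              paste(names(x$timings), sprintf("%.1f", x$timings),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
summary.oct_segmentation <- function(object, ...) {
  maps <- thickness_maps(object$surfaces, object$spacing, object$mode)
  qs <- do.call(rbind, lapply(names(maps), function(nm)
    cbind(layer = nm, quadrant_stats(maps[[nm]], object$spacing))))
  cat(sprintf("Segmentation (%s mode), quadrant layer thickness (um):\n",
              object$mode))
  print(qs, row.names = FALSE, digits = 4)
  invisible(qs)
}

#' Plot a segmented B-scan with surface overlays
#'
#' @param x an `oct_segmentation`.
#' @param volume the segmented [oct_volume()] (for the background image).
#' @param b 0-based B-scan index.
#' @param ... unused.
#' @export
plot.oct_segmentation <- function(x, volume, b = (x$dim[1] - 1) %/% 2, ...) {
  img <- volume$intensity[b + 1L, , ]
  graphics::image(x = 0:(nrow(img) - 1), y = 0:(ncol(img) - 1),
                  z = img[, ncol(img):1],
                  col = grDevices::gray.colors(256, 0, 1), useRaster = TRUE,
                  xlab = "A-scan (x)", ylab = "depth (z, flipped)",
                  main = sprintf("B-scan %d (%s)", b, x$mode))
  Z <- x$dim[3]
  cols <- grDevices::hcl.colors(length(x$surfaces$surfaces), "Dark 3")
  for (i in seq_along(x$surfaces$surfaces)) {
    graphics::lines(0:(x$dim[2] - 1),
                    Z - 1 - x$surfaces$surfaces[[i]][b + 1L, ], col = cols[i])
  }
  invisible(x)
}

#' Train the per-stage boundary classifiers for a mode
#'
#' Convenience wrapper around the full training path: downsample the
#' training volumes, localize their ROIs, extract features, convert the
#' native-resolution delineations to the working grid, and fit one
#' classifier per stage.
#'
#' @param volumes list of native-resolution training [oct_volume()]s.
#' @param delineations list of native-resolution [delineation()]s parallel
#'   to `volumes`.
#' @param mode `"healthy"` or `"ld"`.
#' @param seed integer seed.
#' @param config a [seg_config()].
#' @param ... passed to [train_boundary_classifier()].
#' @return named list of models (`stage1`..`stage3`).
#' @export
train_segmentation_models <- function(volumes, delineations,
                                      mode = c("healthy", "ld"), seed = 1L,
                                      config = NULL, ...) {
  mode <- match.arg(mode)
  if (inherits(volumes, "oct_volume")) volumes <- list(volumes)
  if (inherits(delineations, "delineation")) delineations <- list(delineations)
  if (is.null(config)) config <- seg_config(mode)
  stacks <- list(); delins_ws <- list()
  for (i in seq_along(volumes)) {
    vws <- downsample_volume(volumes[[i]], config$lateral_factor,
                             config$axial_factor)
    roi <- coarse_localize(vws, config)
    stacks[[i]] <- extract_features(vws, roi)
    d <- delineations[[i]]
    slices_ws <- lapply(d$slices, function(sl) {
      p <- sl$points
      list(b = sl$b, surface = sl$surface,
           points = cbind(p[, 1] / config$lateral_factor,
                          p[, 2] / config$axial_factor))
    })
    delins_ws[[i]] <- delineation(d$rater, slices_ws, rule = d$rule,
                                  repeat_id = d$repeat_id)
  }
  plan <- stage_plan(mode)
  models <- lapply(seq_along(plan), function(k)
    train_boundary_classifier(stacks, delins_ws, plan[[k]], mode,
                              seed = seed + k, ...))
  names(models) <- names(plan)
  models
}
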